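# File formats and the command-line surface.
#
# Movies are stored as uncompressed little-endian 32-bit-float grayscale
# multi-page TIFF (axis order TYX, one file per channel; ImageJ-style
# description tag carries frame_rate and pixel_size). No TIFF package is
# available in the target environment, so this is a purpose-built baseline
# codec supporting exactly that layout.

#' Write a movie as multi-page TIFF
#'
#' @param movie \[H, W, T\] numeric array (or a `time_lapse_movie`)
#' @param path output file
#' @param frame_rate,pixel_size,channel metadata stored in the description tag
#' @return `path`, invisibly
#' @export
write_movie <- function(movie, path, frame_rate = 1, pixel_size = 0.1,
                        channel = "phase") {
  if (inherits(movie, "time_lapse_movie")) {
    frame_rate <- movie$frame_rate; pixel_size <- movie$pixel_size
    channel <- movie$channel; movie <- movie$frames
  }
  stopifnot(length(dim(movie)) == 3L)
  H <- dim(movie)[1]; W <- dim(movie)[2]; TT <- dim(movie)[3]
  desc <- sprintf(
    "ImageJ=1.54\nimages=%d\nframes=%d\nfinterval=%.10g\nunit=um\npixel_size=%.10g\nchannel=%s\n",
    TT, TT, 1 / frame_rate, pixel_size, channel)
  descb <- c(charToRaw(desc), as.raw(0))
  if (length(descb) %% 2L) descb <- c(descb, as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  desc_off <- 8L
  page_bytes <- H * W * 4L
  data_off <- desc_off + length(descb)
  ifd_off <- data_off + TT * page_bytes
  if (ifd_off %% 2L) ifd_off <- ifd_off + 1L
  w4(ifd_off)                                   # offset of first IFD
  writeBin(descb, con)
  for (t in seq_len(TT))                        # row-major page data
    writeBin(as.numeric(t(movie[, , t])), con, size = 4, endian = "little")
  if ((data_off + TT * page_bytes) %% 2L) writeBin(as.raw(0), con)
  n_entries <- 11L
  ifd_size <- 2L + n_entries * 12L + 4L
  for (t in seq_len(TT)) {
    w2(n_entries)
    entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count); w4(value) }
    entry(256L, 4L, 1L, W)                      # ImageWidth
    entry(257L, 4L, 1L, H)                      # ImageLength
    entry(258L, 3L, 1L, 32L)                    # BitsPerSample
    entry(259L, 3L, 1L, 1L)                     # no compression
    entry(262L, 3L, 1L, 1L)                     # BlackIsZero
    entry(270L, 2L, length(descb), desc_off)    # ImageDescription
    entry(273L, 4L, 1L, data_off + (t - 1L) * page_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                     # SamplesPerPixel
    entry(278L, 4L, 1L, H)                      # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, 3L)                     # SampleFormat: IEEE float
    w4(if (t < TT) ifd_off + t * ifd_size else 0L)
  }
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Supports the baseline layout written by [write_movie()] (uncompressed
#' little-endian grayscale, one strip per page). The channel is inferred from
#' the description tag or the filename suffix.
#'
#' @param path TIFF file
#' @return object of class `time_lapse_movie`: list(`frames` \[H,W,T\],
#'   `channel`, `frame_rate`, `pixel_size`)
#' @export
read_movie <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" ||
      readBin(raw[3:4], "integer", size = 2, endian = "little") != 42L)
    stop("read_movie: not a little-endian TIFF: ", path)
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2,
                               endian = "little", signed = FALSE)
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4,
                               endian = "little")
  ifd <- u32(4L)
  if (ifd == 0L) stop("read_movie: empty TIFF (no IFD): ", path)
  frames <- list(); desc <- NULL; page <- 0L
  while (ifd != 0L) {
    page <- page + 1L
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
      val <- if (type == 3L) u16(off + 8L) else u32(off + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count, val = val)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags)))
      stop("read_movie: page ", page, ": missing required TIFF tags")
    W <- tags[["256"]]$val; H <- tags[["257"]]$val
    if ((tags[["259"]]$val %||% 1L) != 1L)
      stop("read_movie: page ", page, ": compressed TIFF not supported")
    if ((tags[["339"]]$val %||% 3L) != 3L || (tags[["258"]]$val %||% 32L) != 32L)
      stop("read_movie: page ", page, ": only 32-bit float samples supported")
    if (length(frames) && !identical(dim(frames[[1]]), c(H, W)))
      stop("read_movie: page ", page, ": inconsistent page shape")
    so <- tags[["273"]]$val; sb <- tags[["279"]]$val
    if (sb != H * W * 4L)
      stop("read_movie: page ", page, ": unexpected strip layout")
    v <- readBin(raw[so + seq_len(sb)], "numeric", n = H * W, size = 4,
                 endian = "little")
    frames[[page]] <- matrix(v, H, W, byrow = TRUE)
    if (is.null(desc) && "270" %in% names(tags)) {
      d <- tags[["270"]]
      desc <- rawToChar(raw[d$val + seq_len(d$count - 1L)])
      desc <- sub("\\x00.*$", "", desc)
    }
    ifd <- u32(ifd + 2L + n * 12L)
  }
  meta <- list(frame_rate = 1, pixel_size = NA_real_, channel = NA_character_)
  if (!is.null(desc)) {
    grab <- function(key) {
      m <- regmatches(desc, regexec(paste0(key, "=([^\n]+)"), desc))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    fi <- suppressWarnings(as.numeric(grab("finterval")))
    if (is.finite(fi) && fi > 0) meta$frame_rate <- 1 / fi
    meta$pixel_size <- suppressWarnings(as.numeric(grab("pixel_size")))
    meta$channel <- grab("channel")
  }
  if (is.na(meta$channel)) {
    stem <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
    hit <- CHANNELS[vapply(CHANNELS, function(ch) endsWith(stem, ch), logical(1))]
    meta$channel <- if (length(hit)) hit[1] else "phase"
  }
  structure(list(frames = array(unlist(frames),
                                c(dim(frames[[1]]), length(frames))),
                 channel = meta$channel, frame_rate = meta$frame_rate,
                 pixel_size = meta$pixel_size),
            class = "time_lapse_movie")
}

#' Write / read event tables as CSV
#'
#' Header `event_id,class,polarity,t_start,t_end,x,y`; 0-based inclusive
#' frame spans.
#'
#' @param events event table
#' @param path CSV file
#' @return `path` invisibly (write) / validated event data.frame (read)
#' @export
write_events <- function(events, path) {
  cols <- c("event_id", "class", "polarity", "t_start", "t_end", "x", "y")
  utils::write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "class", "polarity", "t_start", "t_end", "x", "y")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("read_events: missing column(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(ev))) {
    line <- i + 1L                               # header is line 1
    if (ev$t_end[i] < ev$t_start[i])
      stop("read_events: line ", line, ": t_end < t_start")
    if (ev$x[i] < 0 || ev$y[i] < 0 || ev$t_start[i] < 0)
      stop("read_events: line ", line, ": negative coordinate")
  }
  validate_events(ev)
  ev
}

#' Save / load a detector checkpoint (config embedded)
#' @param detector a detector
#' @param path checkpoint file
#' @return `path` invisibly / the restored detector
#' @export
save_detector <- function(detector, path) {
  obj <- list(config = detector$config, params = detector$params,
              trained = detector$trained, loss_history = detector$loss_history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- readRDS(path)
  det <- build_detector(obj$config)
  det$params <- obj$params
  det$trained <- obj$trained
  det$loss_history <- obj$loss_history
  det
}

# ---- configuration + manifest ----------------------------------------------

fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    # xor only touches the low byte (b < 256); keeps h a double within 2^32
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

known_keys <- function() list(
  sim = names(formals(sim_config)),
  train = c(names(formals(detector_config)), "windows_per_event", "channels"),
  controller = names(formals(controller_config)),
  analysis = c("camera_offset", "radius_um", "time_grid_step"))

read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_keys <- known_keys()
  for (sec in names(cfg)) {
    if (!sec %in% c(names(known_keys), "seed", "out"))
      stop("config: unknown section `", sec, "`")
    if (sec %in% names(known_keys)) {
      bad <- setdiff(names(cfg[[sec]]), known_keys[[sec]])
      if (length(bad))
        stop("config: unknown key(s) in `", sec, "`: ",
             paste(bad, collapse = ", "))
    }
  }
  cfg
}

write_manifest <- function(out_dir, config_path, seeds, artifacts) {
  man <- list(config_hash = fnv1a(paste(readLines(config_path), collapse = "\n")),
              config = config_path, seeds = seeds, artifacts = artifacts,
              package_version = as.character(utils::packageVersion("edascope")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

cli_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

parse_argv <- function(argv) {
  opts <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else { opts[[key]] <- argv[i + 1L]; i <- i + 2L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `train`, `evaluate`, `run-eda`, `analyze`. Every
#' run honors `--seed` and writes a `manifest.json` into the output
#' directory. See `inst/cli/eda.R` for the Rscript wrapper.
#'
#' @param argv character vector of arguments (default: command line)
#' @return exit status (0 on success), invisibly
#' @export
eda_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv)) stop("usage: eda <simulate|train|evaluate|run-eda|analyze> ...")
    cmd <- argv[1]
    pa <- parse_argv(argv[-1])
    o <- pa$opts
    seed <- as.integer(o$seed %||% 1L)
    out_dir <- o$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    switch(cmd,
      "simulate" = {
        cfgp <- o$config %||% stop("simulate: --config required")
        xc <- read_experiment_config(cfgp)
        sim_args <- xc$sim %||% list()
        sim_args$seed <- seed
        cfg <- do.call(sim_config, sim_args)
        cli_log("simulate", "rendering %d frames at %dx%d",
                n_frames(cfg), cfg$height, cfg$width)
        traj <- simulate_sample(cfg)
        TT <- traj$n_frames
        mv <- array(0, c(cfg$height, cfg$width, TT))
        for (t in 0:(TT - 1L))
          mv[, , t + 1L] <- render_phase_frame(state_at(traj, t), cfg)
        paths <- c(file.path(out_dir, "movie_phase.tif"),
                   file.path(out_dir, "events.csv"))
        write_movie(mv, paths[1], cfg$frame_rate, cfg$pixel_size, "phase")
        write_events(traj$events, paths[2])
        write_manifest(out_dir, cfgp, seed, paths)
        cli_log("simulate", "wrote %s", paste(paths, collapse = ", "))
      },
      "train" = {
        cfgp <- o$config %||% stop("train: --config required")
        datad <- o$data %||% stop("train: --data required")
        runs <- as.integer(o$runs %||% 1L)
        xc <- read_experiment_config(cfgp)
        mv <- read_movie(file.path(datad, "movie_phase.tif"))
        ev <- read_events(file.path(datad, "events.csv"))
        targs <- xc$train %||% list()
        wpe <- targs$windows_per_event %||% 5L
        targs$windows_per_event <- NULL; targs$channels <- NULL
        best <- NULL
        for (r in seq_len(runs)) {
          targs$seed <- seed + r - 1L
          dcfg <- do.call(detector_config, targs)
          ts <- make_training_set(mv$frames, ev, dcfg$n_time_points,
                                  dcfg$sigma_label, windows_per_event = wpe)
          det <- train_detector(build_detector(dcfg), ts)
          sc <- evaluate_on_validation(det, ts, ev)
          cli_log("train", "run %d/%d: validation F0.1 %.3f", r, runs,
                  sc$scores$f_beta)
          if (is.null(best) || sc$scores$f_beta > best$scores$f_beta)
            best <- list(detector = det, scores = sc$scores)
        }
        mp <- file.path(out_dir, "model.rds")
        save_detector(best$detector, mp)
        jsonlite::write_json(best$scores, file.path(out_dir, "scores.json"),
                             auto_unbox = TRUE, digits = NA)
        write_manifest(out_dir, cfgp, seed + seq_len(runs) - 1L, mp)
      },
      "evaluate" = {
        mp <- o$model %||% stop("evaluate: --model required")
        datad <- o$data %||% stop("evaluate: --data required")
        beta <- as.numeric(o$beta %||% 0.1)
        det <- load_detector(mp)
        mv <- read_movie(file.path(datad, "movie_phase.tif"))
        ev <- read_events(file.path(datad, "events.csv"))
        maps <- infer_sequence(det, mv$frames)
        opt <- optimize_threshold(maps, ev, beta = beta)
        rep <- data.frame(run_id = basename(mp), threshold = opt$threshold,
                          P = opt$scores$precision, R = opt$scores$recall,
                          f01 = opt$scores$f_beta)
        utils::write.csv(rep, file.path(out_dir, "evaluation.csv"),
                         row.names = FALSE)
        jsonlite::write_json(opt$scores, file.path(out_dir, "evaluation.json"),
                             auto_unbox = TRUE, digits = NA)
        cli_log("evaluate", "F_%.2g %.3f at threshold %.2f", beta,
                opt$scores$f_beta, opt$threshold)
      },
      "run-eda" = {
        cfgp <- o$sim %||% stop("run-eda: --sim required")
        xc <- read_experiment_config(cfgp)
        sim_args <- xc$sim %||% list(); sim_args$seed <- seed
        cfg <- do.call(sim_config, sim_args)
        traj <- simulate_sample(cfg)
        ctrl <- do.call(controller_config, xc$controller %||% list())
        det <- if (!is.null(o$model) && !isTRUE(o$model)) load_detector(o$model)
               else oracle_detector(traj$events, c(cfg$height, cfg$width))
        render <- isTRUE(det$needs_pixels) || is.null(det$needs_pixels)
        log <- run_eda(traj, det, ctrl, render = render)
        utils::write.csv(as.data.frame(log), file.path(out_dir, "acquisition_log.csv"),
                         row.names = FALSE)
        st <- capture_stats(log, traj$events)
        jsonlite::write_json(st[c("duty_cycle", "events_captured_fraction",
                                  "fluorescence_frames_per_captured_event")],
                             file.path(out_dir, "capture_stats.json"),
                             auto_unbox = TRUE, digits = NA)
        write_manifest(out_dir, cfgp, seed,
                       file.path(out_dir, "acquisition_log.csv"))
        cli_log("run-eda", "duty cycle %.3f, captured %.0f%%", st$duty_cycle,
                100 * st$events_captured_fraction)
      },
      "analyze" = {
        what <- pa$pos[1] %||% stop("analyze: need survival|dutycycle")
        if (identical(what, "dutycycle")) {
          model <- duty_cycle_model(as.numeric(o$interval %||% 3.1),
                                    as.numeric(o$duration %||% 20),
                                    as.numeric(o$rate %||% 1))
          res <- list(continuous_frames = continuous_frames_per_event(model),
                      fold_reduction = fold_reduction(model,
                        as.numeric(o$triggered %||% 20)))
          jsonlite::write_json(res, file.path(out_dir, "dutycycle.json"),
                               auto_unbox = TRUE, digits = NA)
        } else if (identical(what, "survival")) {
          tab <- utils::read.csv(o[["in"]] %||% stop("analyze survival: --in required"))
          grid <- seq(0, max(tab$death_time), length.out = 50)
          cur <- survival_curve(tab, grid)
          fit <- fit_decay(cur)
          jsonlite::write_json(list(k = fit$k, half_life = fit$half_life),
                               file.path(out_dir, "survival_fit.json"),
                               auto_unbox = TRUE, digits = NA)
        } else stop("analyze: unknown analysis `", what, "`")
      },
      stop("unknown subcommand `", cmd, "`")
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# Convenience used by the train subcommand: optimized-threshold scores on the
# validation windows of a training set.
evaluate_on_validation <- function(detector, training_set, events,
                                   beta = 0.1) {
  va <- which(training_set$split == "validation")
  if (!length(va)) stop("no validation windows")
  d <- dim(training_set$x)
  maps <- lapply(va, function(i) {
    detector <- reset_state(detector)
    infer(detector, array(training_set$x[, , i, ], c(d[1], d[2], d[4])))
  })
  # windows of different events come from different movies: shift each event
  # onto a disjoint stretch of the time axis so detection grouping and
  # matching never cross event boundaries
  ev_ids <- sort(unique(training_set$event_id[va]))
  offset_of <- stats::setNames((seq_along(ev_ids) - 1L) * 1000L, ev_ids)
  frame_ts <- training_set$t_end[va] +
    offset_of[as.character(training_set$event_id[va])]
  ev <- events[events$event_id %in% ev_ids, , drop = FALSE]
  off <- offset_of[as.character(ev$event_id)]
  ev$t_start <- ev$t_start + off
  ev$t_end <- ev$t_end + off
  optimize_threshold(maps, ev, beta = beta, frame_ts = frame_ts)
}
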