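ten_twenty_labels <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3",
                       "C4", "Cz", "T3", "T4", "T5", "T6", "P3", "P4", "Pz",
                       "O1", "O2")

#' Multichannel recording
#'
#' Container for one subject's multichannel record: a channels-by-samples
#' numeric matrix with unique channel labels, the sampling frequency, and
#' free-form subject metadata (id, group, age, handedness, ...).
#'
#' @param data Numeric matrix, channels x samples; row names are used as
#'   labels when `labels` is missing.
#' @param labels Character vector of unique channel labels.
#' @param fs Sampling frequency, Hz.
#' @param meta Named list of subject metadata.
#' @return An object of class `recording`.
#' @export
recording <- function(data, labels = rownames(data), fs, meta = list()) {
  data <- as.matrix(data)
  if (is.null(labels)) stop("channel labels are required", call. = FALSE)
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (length(labels) != nrow(data)) {
    stop("one label per channel row is required", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs", positive = TRUE)
  rownames(data) <- labels
  structure(list(data = data, labels = labels, fs = fs, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples (%.3g s at %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a recording from a delimited matrix
#'
#' Reads a channels-by-samples delimited text file whose first column holds
#' the channel label. Labels outside the 10-20 montage produce a warning but
#' the channel is retained; sampling rates other than 256 or 500 Hz are
#' warned about as unusual for this kind of data.
#'
#' @param path File path.
#' @param fs Sampling frequency of the stored samples, Hz.
#' @param delim Field delimiter (default tab).
#' @param meta Named list of subject metadata to attach.
#' @return A [recording()].
#' @export
read_recording <- function(path, fs, delim = "\t", meta = list()) {
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           stringsAsFactors = FALSE)
  labels <- as.character(raw[[1L]])
  dat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(dat) <- "double"
  dimnames(dat) <- NULL
  unknown <- setdiff(labels, ten_twenty_labels)
  if (length(unknown) > 0L) {
    warning("channel label(s) outside the 10-20 montage retained: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!fs %in% c(256, 500)) {
    warning(sprintf("unusual sampling rate %g Hz (expected 256 or 500)", fs),
            call. = FALSE)
  }
  recording(dat, labels = labels, fs = fs, meta = meta)
}

#' Write a recording as a delimited matrix
#'
#' Inverse of [read_recording()]: channel label in the first column, samples
#' in the remaining columns.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, delim = "\t") {
  stopifnot(inherits(rec, "recording"))
  df <- data.frame(label = rec$labels, rec$data, check.names = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to delimited files plus a metadata table
#'
#' One file per (subject, segment) recording, named
#' `<subject>_seg<k>.tsv`, and a `metadata.tsv` table with columns
#' `subject`, `group`, `segment`, `file`, `fs`.
#'
#' @param cohort Tibble as returned by [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The metadata tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- dplyr::mutate(
    cohort[, c("subject", "group", "segment")],
    file = sprintf("%s_seg%d.tsv", .data$subject, .data$segment),
    fs = vapply(cohort$recording, function(r) r$fs, 1.0)
  )
  for (i in seq_len(nrow(cohort))) {
    write_recording(cohort$recording[[i]], file.path(dir, meta$file[i]))
  }
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(tibble::as_tibble(meta))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `metadata.tsv` and the per-segment files.
#' @return A cohort tibble (`subject`, `group`, `segment`, `recording`).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    suppressWarnings(read_recording(
      file.path(dir, meta$file[i]), fs = meta$fs[i],
      meta = list(subject = meta$subject[i], group = meta$group[i],
                  segment = meta$segment[i])
    ))
  })
  tibble::tibble(subject = meta$subject,
                 group = factor(as.character(meta$group)),
                 segment = meta$segment, recording = recs)
}

#' Preprocess a recording
#'
#' Default preprocessing applied before connectivity analysis: per-channel
#' mean removal, removal of slow drifts below `highpass` Hz with a
#' zero-phase Butterworth filter, and an optional 50/60 Hz notch. Every
#' enabled step is recorded in the returned object's metadata under
#' `$meta$preprocessing`. With all steps disabled the recording is returned
#' unchanged.
#'
#' @param rec A [recording()].
#' @param demean Remove the per-channel mean.
#' @param highpass Drift cutoff, Hz, or `NULL` to skip.
#' @param notch Mains frequency (e.g. 50 or 60), or `NULL` to skip.
#' @return The preprocessed [recording()].
#' @export
preprocess <- function(rec, demean = TRUE, highpass = 0.5, notch = NULL) {
  stopifnot(inherits(rec, "recording"))
  steps <- character()
  dat <- rec$data
  if (demean) {
    dat <- dat - rowMeans(dat)
    steps <- c(steps, "demean")
  }
  if (!is.null(highpass)) {
    bf <- signal::butter(2, highpass / (rec$fs / 2), type = "high")
    for (i in seq_len(nrow(dat))) dat[i, ] <- signal::filtfilt(bf, dat[i, ])
    steps <- c(steps, sprintf("highpass_%gHz", highpass))
  }
  if (!is.null(notch)) {
    bf <- signal::butter(2, c(notch - 1, notch + 1) / (rec$fs / 2),
                         type = "stop")
    for (i in seq_len(nrow(dat))) dat[i, ] <- signal::filtfilt(bf, dat[i, ])
    steps <- c(steps, sprintf("notch_%gHz", notch))
  }
  out <- rec
  out$data <- dat
  out$meta$preprocessing <- c(rec$meta$preprocessing, steps)
  out
}

#' Cut a recording into analysis segments
#'
#' Three segmentation modes: `"sequential"` takes `n` non-overlapping
#' segments of `length` seconds from the start of the record; `"central"`
#' takes the middle `length` seconds; `"explicit"` takes segments starting
#' at the given `starts` (seconds).
#'
#' @param rec A [recording()].
#' @param mode Segmentation mode.
#' @param length Segment length, seconds (default 180, i.e. 3 min).
#' @param n Number of sequential segments (default 5).
#' @param starts Numeric start times (seconds) for `"explicit"` mode.
#' @return A list of [recording()] objects with segment metadata.
#' @export
plan_segments <- function(rec, mode = c("sequential", "central", "explicit"),
                          length = 180, n = 5, starts = NULL) {
  stopifnot(inherits(rec, "recording"))
  mode <- match.arg(mode)
  total <- ncol(rec$data) / rec$fs
  L <- round(length * rec$fs)
  starts <- switch(mode,
    sequential = (seq_len(n) - 1L) * length,
    central = (total - length) / 2,
    explicit = starts %||% stop("`starts` required for explicit mode",
                                call. = FALSE)
  )
  if (any(starts < 0) || any(starts + length > total + 1e-9)) {
    stop(sprintf(
      "record of %.3g s cannot hold the requested segment(s) of %g s", total,
      length), call. = FALSE)
  }
  lapply(seq_along(starts), function(k) {
    i0 <- round(starts[k] * rec$fs)
    seg <- rec
    seg$data <- rec$data[, (i0 + 1L):(i0 + L), drop = FALSE]
    seg$meta$segment <- k
    seg$meta$segment_start <- starts[k]
    seg
  })
}

#' Run the full phase-connectivity pipeline on a cohort
#'
#' Chains, for every probe pair and segment: wavelet transform of each
#' channel, phase extraction, time-averaged wavelet phase coherence per
#' subject, the per-group intersubject surrogate pool, and effective
#' (surrogate-subtracted, band-averaged) coherence; then the group
#' statistics (rank-sum, Cohen's d, and, when several segments are present,
#' the shuffled-segment test). Optionally also runs the windowed dynamical
#' Bayesian inference per pair direction, thresholds the per-window coupling
#' strengths at the 95th percentile of the intersubject null, and compares
#' the resulting percentage coupling times between groups.
#'
#' @param cohort Cohort tibble (`subject`, `group`, `segment`, `recording`),
#'   as from [generate_cohort()] or [read_cohort()].
#' @param pairs List of character length-2 probe pairs to analyse.
#' @param band Analysis band, Hz.
#' @param wavelet Optional [wavelet_params()]; defaults to the band with
#'   standard settings at the cohort's sampling rate.
#' @param run_dbi Also compute coupling times via Bayesian inference
#'   (slower).
#' @param dbi A [dbi_config()] used when `run_dbi = TRUE`.
#' @param n_shuffles Shuffles for the repeatability test (when > 1 segment).
#' @param seed Optional seed for the shuffle test.
#' @param window_cycles Coherence window, cycles.
#' @return A list of class `phaseconn_results`:
#'   \describe{
#'     \item{coherence}{tibble: subject, group, segment, pair, value
#'       (effective coherence)}
#'     \item{coupling}{tibble (when `run_dbi`): subject, group, segment,
#'       pair, direction, value (% time coupled)}
#'     \item{stats}{tibble of per-pair (and direction) group comparisons}
#'     \item{manifest}{settings, seed, and a content hash of the settings}
#'   }
#' @export
run_pipeline <- function(cohort, pairs, band = c(3.5, 12), wavelet = NULL,
                         run_dbi = FALSE, dbi = dbi_config(band = band),
                         n_shuffles = 1000, seed = NULL, window_cycles = 10) {
  stopifnot(all(c("subject", "group", "segment", "recording") %in% names(cohort)))
  fs <- cohort$recording[[1L]]$fs
  wavelet <- wavelet %||% wavelet_params(fs = fs, fmin = band[1], fmax = band[2])
  channels <- unique(unlist(pairs))
  segments <- sort(unique(cohort$segment))
  glev <- levels(factor(as.character(cohort$group)))

  coh_rows <- list()
  cpl_rows <- list()
  for (seg in segments) {
    sub <- cohort[cohort$segment == seg, ]
    # phase fields per subject x channel
    fields <- lapply(seq_len(nrow(sub)), function(i) {
      r <- sub$recording[[i]]
      out <- lapply(channels, function(ch) {
        extract_phase(wavelet_transform(r$data[ch, ], wavelet))
      })
      names(out) <- channels
      out
    })
    for (pp in pairs) {
      pair_lab <- paste(pp, collapse = "-")
      for (g in glev) {
        gi <- which(as.character(sub$group) == g)
        f1 <- lapply(fields[gi], `[[`, pp[1L])
        f2 <- lapply(fields[gi], `[[`, pp[2L])
        pool <- intersubject_pool(f1, f2, pair = pp,
                                  window_cycles = window_cycles)
        for (k in seq_along(gi)) {
          tlc <- time_localized_wpc(f1[[k]], f2[[k]],
                                    window_cycles = window_cycles)
          eff <- effective_coherence(time_avg_wpc(tlc), pool, band = band)
          coh_rows[[length(coh_rows) + 1L]] <- tibble::tibble(
            subject = sub$subject[gi[k]], group = g, segment = seg,
            pair = pair_lab, value = as.numeric(eff)
          )
        }
        if (run_dbi) {
          cpl_rows <- c(cpl_rows, dbi_group_rows(sub, gi, pp, g, seg, dbi, fs))
        }
      }
    }
  }
  coherence <- dplyr::bind_rows(coh_rows)
  coupling <- if (run_dbi) dplyr::bind_rows(cpl_rows) else NULL

  stats_tbl <- summarize_group_stats(coherence, glev, n_shuffles, seed)
  if (run_dbi) {
    cstats <- summarize_group_stats(coupling, glev, n_shuffles, seed,
                                    by_direction = TRUE)
    stats_tbl <- dplyr::bind_rows(
      dplyr::mutate(stats_tbl, measure = "wpc", .before = 1L),
      dplyr::mutate(cstats, measure = "dbi", .before = 1L)
    )
  } else {
    stats_tbl <- dplyr::mutate(stats_tbl, measure = "wpc", .before = 1L)
  }
  settings <- list(band = band, window_cycles = window_cycles,
                   pairs = vapply(pairs, paste, "", collapse = "-"),
                   fs = fs, run_dbi = run_dbi, n_shuffles = n_shuffles,
                   seed = seed)
  manifest <- list(
    settings = settings,
    config_hash = config_hash(settings),
    n_subjects = length(unique(cohort$subject)),
    segments = segments
  )
  structure(list(coherence = coherence, coupling = coupling,
                 stats = stats_tbl, manifest = manifest),
            class = "phaseconn_results")
}

# DBI branch of the pipeline: per-subject coupling times for one pair within
# one group, thresholded at the 95th percentile of the cross-subject null.
dbi_group_rows <- function(sub, gi, pp, g, seg, config, fs) {
  phases <- lapply(gi, function(i) {
    r <- sub$recording[[i]]
    list(a = extract_band_phase(r$data[pp[1L], ], config$band, fs),
         b = extract_band_phase(r$data[pp[2L], ], config$band, fs))
  })
  n <- length(phases)
  null_ab <- c(); null_ba <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      fit <- fit_windows(phases[[i]]$a, phases[[j]]$b, config, fs)
      null_ab <- c(null_ab, mean(fit$windows$strength_ab))
      null_ba <- c(null_ba, mean(fit$windows$strength_ba))
    }
  }
  thr_ab <- coupling_threshold(null_ab)
  thr_ba <- coupling_threshold(null_ba)
  rows <- list()
  for (k in seq_len(n)) {
    fit <- fit_windows(phases[[k]]$a, phases[[k]]$b, config, fs)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject = sub$subject[gi[k]], group = g, segment = seg,
      pair = paste(pp, collapse = "-"),
      direction = c(paste0(pp[1L], "->", pp[2L]), paste0(pp[2L], "->", pp[1L])),
      value = c(coupling_time(fit$windows$strength_ab, thr_ab),
                coupling_time(fit$windows$strength_ba, thr_ba))
    )
  }
  rows
}

summarize_group_stats <- function(values, glev, n_shuffles, seed,
                                  by_direction = FALSE) {
  keys <- if (by_direction) c("pair", "direction") else "pair"
  groups <- dplyr::group_split(dplyr::group_by(
    values, dplyr::across(dplyr::all_of(keys))))
  rows <- lapply(groups, function(d) {
    per_seg <- lapply(sort(unique(d$segment)), function(seg) {
      ds <- d[d$segment == seg, ]
      a <- ds$value[as.character(ds$group) == glev[1L]]
      b <- ds$value[as.character(ds$group) == glev[2L]]
      rs <- rank_sum(a, b)
      tibble::tibble(segment = seg, p_value = rs$p_value,
                     cohens_d = suppressWarnings(cohens_d(a, b)))
    })
    per_seg <- dplyr::bind_rows(per_seg)
    shuf <- if (length(unique(d$segment)) >= 2L) {
      shuffled_segment_test(d, n_shuffles = n_shuffles, seed = seed)$percent_significant
    } else {
      NA_real_
    }
    out <- tibble::tibble(pair = d$pair[1L])
    if (by_direction) out$direction <- d$direction[1L]
    out$per_segment <- list(per_seg)
    out$min_p <- min(per_seg$p_value)
    out$median_p <- stats::median(per_seg$p_value)
    out$shuffled_percent <- shuf
    out
  })
  dplyr::bind_rows(rows)
}

config_hash <- function(settings) {
  # small content hash (djb2) of the deparsed settings; avoids a digest
  # dependency while still detecting config changes in the manifest
  s <- paste(deparse(settings), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Group-median connectivity heatmap matrix
#'
#' Probe-by-probe matrix of group-median values for one group and segment:
#' symmetric for coherence values, asymmetric (directional) for coupling
#' times.
#'
#' @param values Tibble with `pair` (and optionally `direction`), `group`,
#'   `segment`, `value` columns (from [run_pipeline()] results).
#' @param group Group level to summarize.
#' @param segment Segment to summarize.
#' @return A named numeric matrix.
#' @export
heatmap_matrix <- function(values, group, segment = 1) {
  d <- values[as.character(values$group) == as.character(group) &
                values$segment == segment, ]
  directional <- "direction" %in% names(d) && !is.null(d$direction)
  if (directional) {
    from <- sub("->.*$", "", d$direction)
    to <- sub("^.*->", "", d$direction)
  } else {
    from <- sub("-.*$", "", d$pair)
    to <- sub("^.*-", "", d$pair)
  }
  probes <- sort(unique(c(from, to)))
  m <- matrix(NA_real_, length(probes), length(probes),
              dimnames = list(probes, probes))
  agg <- stats::aggregate(d$value, list(from = from, to = to), stats::median)
  for (i in seq_len(nrow(agg))) {
    m[agg$from[i], agg$to[i]] <- agg$x[i]
    if (!directional) m[agg$to[i], agg$from[i]] <- agg$x[i]
  }
  m
}

#' Write pipeline results to delimited/JSON files
#'
#' Writes `coherence.csv`, `coupling_time.csv` (when present),
#' `group_stats.json` and `manifest.json` under `dir`.
#'
#' @param results A `phaseconn_results` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "phaseconn_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(results$coherence, file.path(dir, "coherence.csv"),
                   row.names = FALSE)
  if (!is.null(results$coupling)) {
    utils::write.csv(results$coupling, file.path(dir, "coupling_time.csv"),
                     row.names = FALSE)
  }
  stats_out <- results$stats
  stats_out$per_segment <- lapply(stats_out$per_segment, as.data.frame)
  jsonlite::write_json(stats_out, file.path(dir, "group_stats.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.phaseconn_results <- function(x, ...) {
  cat(sprintf(
    "<phaseconn_results> %d effective-coherence values, %d pairs, %d segment(s)\n",
    nrow(x$coherence), length(unique(x$coherence$pair)),
    length(unique(x$coherence$segment))))
  if (!is.null(x$coupling)) {
    cat(sprintf("  + %d coupling-time values\n", nrow(x$coupling)))
  }
  invisible(x)
}
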