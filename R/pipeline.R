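#' Analysis pipeline configuration
#'
#' All tunable parameters of the analysis chain in one validated list.
#' Defaults follow the reference motor-task protocol: 1-100 Hz order-4
#' zero-phase Butterworth band-pass plus 50 Hz notch, epochs from 2 s before
#' to 12 s after the first cue, a 500-sample (2 s at 250 Hz) floating window
#' stepped by 25 samples with centre anchoring, order-1 detrending over
#' scales 8-125, and a 2 s slope fit from each segment onset.
#'
#' @param ... name-value overrides of the defaults; unknown names are
#'   rejected.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter = TRUE,            # apply band-pass + notch before epoching
    bandpass_low_hz = 1, bandpass_high_hz = 100, bandpass_order = 4,
    notch_hz = 50, notch_q = 30,
    pre_s = 2, post_s = 12,   # epoch extent around the first cue
    window = 500, step = 25, anchor = "center",
    detrend_order = 1, n_min = 8, n_max = 125, n_scales = 10,
    fit_interval_s = 2,       # slope fit length from each segment onset
    test_alpha = 0.05,
    seed = NULL
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

#' Analyse one subject's recording
#'
#' Filters the recording (optional), extracts kept epochs, computes the
#' floating-window alpha trajectory per epoch and channel, normalizes the
#' clench and unclench segments, averages trials per hand condition, and
#' fits the response slope per channel x segment x hand condition.
#'
#' @param recording an `eeg_recording`.
#' @param events an `event_table`.
#' @param config a [pipeline_config()].
#' @param channels channel subset to analyse (default all).
#' @return list with `slopes` (data frame: channel, segment,
#'   hand_condition, r, stderr, n_trials) and `curves` (nested list of
#'   subject-level `group_curve` objects indexed `[[channel]][[segment]][[condition]]`).
#' @export
analyze_subject <- function(recording, events, config = pipeline_config(),
                            channels = recording$channel_labels) {
  stopifnot(inherits(recording, "eeg_recording"))
  channels <- intersect(channels, recording$channel_labels)
  if (length(channels) == 0L) stop("no requested channel present")
  rec <- recording
  if (isTRUE(config$filter)) {
    rec <- bandpass_filter(rec, config$bandpass_low_hz,
                           config$bandpass_high_hz, config$bandpass_order)
    rec <- notch_filter(rec, config$notch_hz, config$notch_q)
  }
  eps <- extract_epochs(rec, events, config$pre_s, config$post_s)
  if (length(eps) == 0L) stop("no usable epochs")
  fit_len <- config$fit_interval_s
  # normalized responses per channel/segment, tagged with hand
  resp <- list()
  for (ep in eps) {
    t_un <- ep$unclench_s - ep$onset_s
    for (ch in channels) {
      traj <- sliding_alpha(ep$samples[, ch], ep$sampling_rate,
                            window_len = config$window, step = config$step,
                            anchor = config$anchor,
                            detrend_order = config$detrend_order,
                            n_min = config$n_min, n_max = config$n_max,
                            n_scales = config$n_scales,
                            t0 = -ep$t0_offset_s)
      for (seg in c("clench", "unclench")) {
        t0s <- if (seg == "clench") 0 else t_un
        r <- tryCatch(
          normalize_segment(traj, t0s, t0s + fit_len, segment = seg),
          error = function(e) NULL)
        if (is.null(r)) next
        key <- paste(ch, seg, sep = ".")
        resp[[key]] <- c(resp[[key]], list(c(r, list(hand = ep$hand))))
      }
    }
  }
  conds <- list(all = c("LH", "RH"), LH = "LH", RH = "RH")
  slopes <- list()
  curves <- list()
  for (key in names(resp)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ch <- parts[1]; seg <- parts[2]
    for (cn in names(conds)) {
      rs <- Filter(function(r) r$hand %in% conds[[cn]], resp[[key]])
      if (length(rs) == 0L) next
      cu <- average_trials(rs)
      sl <- estimate_slope(cu, c(0, fit_len))
      curves[[ch]][[seg]][[cn]] <- cu
      slopes[[length(slopes) + 1L]] <- data.frame(
        channel = ch, segment = seg, hand_condition = cn,
        r = sl$r, stderr = sl$stderr, n_trials = cu$n)
    }
  }
  list(slopes = do.call(rbind, slopes), curves = curves)
}

#' Analyse a whole cohort
#'
#' Runs [analyze_subject()] for every subject and assembles per-subject
#' slopes, group-averaged response curves with their group-level slopes, the
#' inter-group statistical report, the LH-RH contrast per group, and the
#' per-channel group difference map.
#'
#' @param cohort a `windfa_cohort` (or a list with the same shape:
#'   `subjects`, each with `id`, `group`, `recording`, `events`).
#' @param config a [pipeline_config()].
#' @param channels channel subset to analyse (default: all channels of the
#'   first subject).
#' @param map_cell list selecting the channel-map / contrast cell, default
#'   `list(segment = "clench", hand_condition = "all")`.
#' @return object of class `windfa_analysis`: list with `slopes`
#'   (per-subject), `group_slopes` (fits on group-averaged curves),
#'   `group_curves`, `report` (from [compare_groups()]), `contrast` (LH-RH,
#'   per group), `channel_map`, `config`, `config_hash`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           channels = NULL,
                           map_cell = list(segment = "clench",
                                           hand_condition = "all")) {
  subjects <- cohort$subjects
  stopifnot(length(subjects) >= 1L)
  if (is.null(channels)) channels <- subjects[[1]]$recording$channel_labels
  slopes <- list()
  sub_curves <- list()
  for (su in subjects) {
    res <- analyze_subject(su$recording, su$events, config, channels)
    sl <- res$slopes
    sl$subject <- su$id
    sl$group <- su$group
    slopes[[length(slopes) + 1L]] <- sl
    sub_curves[[su$id]] <- list(group = su$group, curves = res$curves)
  }
  slopes <- do.call(rbind, slopes)
  groups <- unique(slopes$group)
  # group-averaged curves and their slopes
  group_curves <- list()
  group_slopes <- list()
  for (g in groups) {
    ids <- names(Filter(function(x) x$group == g, sub_curves))
    for (ch in channels) for (seg in c("clench", "unclench"))
      for (cn in c("all", "LH", "RH")) {
        cus <- lapply(ids, function(id) sub_curves[[id]]$curves[[ch]][[seg]][[cn]])
        cus <- Filter(Negate(is.null), cus)
        if (length(cus) == 0L) next
        gc <- suppressWarnings(average_subjects(cus))
        group_curves[[g]][[ch]][[seg]][[cn]] <- gc
        sl <- estimate_slope(gc, c(0, config$fit_interval_s))
        group_slopes[[length(group_slopes) + 1L]] <- data.frame(
          group = g, channel = ch, segment = seg, hand_condition = cn,
          r = sl$r, stderr = sl$stderr, n_subjects = gc$n)
      }
  }
  group_slopes <- do.call(rbind, group_slopes)
  report <- if (length(groups) == 2L)
    compare_groups(slopes, alpha = config$test_alpha) else NULL
  # LH-RH contrast per group (per-subject slopes at hand conditions)
  contrast <- lapply(stats::setNames(groups, groups), function(g) {
    s <- slopes[slopes$group == g & slopes$hand_condition %in% c("LH", "RH"), ]
    s$hand <- s$hand_condition
    # average the two segments per subject/channel/hand before contrasting
    s <- aggregate(s["r"], by = s[c("subject", "channel", "hand")], FUN = mean)
    lh_rh_contrast(s)
  })
  channel_map <- NULL
  if (length(groups) == 2L) {
    gs <- group_slopes[group_slopes$segment == map_cell$segment &
                       group_slopes$hand_condition == map_cell$hand_condition, ]
    ga <- gs[gs$group == groups[1], ]
    gb <- gs[gs$group == groups[2], ]
    ra <- stats::setNames(ga$r, ga$channel)
    rb <- stats::setNames(gb$r, gb$channel)
    # orient as elderly - young when those labels are present
    if (all(sort(groups) == c("elderly", "young"))) {
      re <- if (groups[1] == "elderly") ra else rb
      ry <- if (groups[1] == "elderly") rb else ra
      channel_map <- channel_difference_map(re, ry)
    } else {
      channel_map <- channel_difference_map(ra, rb)
    }
  }
  structure(list(slopes = slopes, group_slopes = group_slopes,
                 group_curves = group_curves, report = report,
                 contrast = contrast, channel_map = channel_map,
                 config = config, config_hash = config_hash(config)),
            class = "windfa_analysis")
}

#' @export
print.windfa_analysis <- function(x, ...) {
  cat("windfa_analysis of", length(unique(x$slopes$subject)), "subjects,",
      length(unique(x$slopes$channel)), "channel(s)\n")
  if (!is.null(x$report)) {
    cat("significant cells (p <", attr(x$report, "alpha"), "):\n")
    print(x$report[x$report$significant,
                   c("channel", "segment", "hand_condition", "p_value")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Run the full simulate-or-load / analyse / report pipeline
#'
#' Either simulates a cohort from `cohort` (a `cohort_spec` or
#' `windfa_cohort`) or loads recordings and event tables from
#' `input_dir` (pairs `<id>_recording.csv` / `<id>_events.tsv`, with group
#' taken from the id prefix before the first underscore), analyses every
#' subject, and writes the slope, group-curve, statistics, contrast and
#' channel-map tables plus a JSON run log to `out_dir`.  Deterministic given
#' the config and the cohort seed.
#'
#' @param cohort a [cohort_spec()] or pre-generated `windfa_cohort`
#'   (mutually exclusive with `input_dir`).
#' @param input_dir directory of recordings/events to load instead.
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if missing.  `NULL` skips
#'   writing.
#' @param channels channel subset to analyse.
#' @return the `windfa_analysis`, invisibly if `out_dir` is set.
#' @export
run_pipeline <- function(cohort = NULL, input_dir = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         channels = NULL) {
  if (is.null(cohort) == is.null(input_dir))
    stop("supply exactly one of 'cohort' or 'input_dir'")
  if (!is.null(cohort)) {
    if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort, config)
    if (!inherits(cohort, "windfa_cohort")) stop("stage simulate: invalid cohort")
  } else {
    cohort <- tryCatch(load_cohort(input_dir),
                       error = function(e) stop("stage load: ", conditionMessage(e)))
  }
  an <- tryCatch(analyze_cohort(cohort, config, channels = channels),
                 error = function(e) stop("stage analyze: ", conditionMessage(e)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- an$config_hash
    wt <- function(df, file) {
      path <- file.path(out_dir, file)
      con <- file(path, "w")
      writeLines(paste0("# windfa config_hash=", h), con)
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
    wt(an$slopes, "subject_slopes.tsv")
    wt(an$group_slopes, "group_slopes.tsv")
    if (!is.null(an$report)) wt(an$report, "stats.tsv")
    if (!is.null(an$channel_map)) wt(an$channel_map, "channel_map.tsv")
    ctr <- do.call(rbind, lapply(names(an$contrast), function(g) {
      co <- an$contrast[[g]]
      data.frame(group = g, mean_abs = co$mean_abs, se_abs = co$se_abs,
                 mean_signed = co$mean_signed, se_signed = co$se_signed,
                 n_subjects = co$n_subjects)
    }))
    wt(ctr, "lh_rh_contrast.tsv")
    gcl <- list()
    for (g in names(an$group_curves))
      for (ch in names(an$group_curves[[g]]))
        for (seg in names(an$group_curves[[g]][[ch]]))
          for (cn in names(an$group_curves[[g]][[ch]][[seg]])) {
            cu <- an$group_curves[[g]][[ch]][[seg]][[cn]]
            gcl[[length(gcl) + 1L]] <- data.frame(
              group = g, channel = ch, segment = seg, hand_condition = cn,
              time_s = cu$times, mean = cu$mean, se = cu$se, n = cu$n)
          }
    wt(do.call(rbind, gcl), "group_curves.tsv")
    log <- list(config = unclass(config), config_hash = h,
                n_subjects = length(cohort$subjects),
                channels = if (is.null(channels))
                  cohort$subjects[[1]]$recording$channel_labels else channels,
                package_version = as.character(utils::packageVersion("windfa")),
                timestamp = format(Sys.time(), tz = "UTC"))
    writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(out_dir, "run_log.json"))
    return(invisible(an))
  }
  an
}
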