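# Readers/writers: plain-text session archive (wide CSV + JSON sidecar),
# model serialization to JSON, run configuration in YAML, and run manifests.

#' Write a trial set to a CSV archive with a JSON sidecar
#'
#' The archive is `<path>.csv` (columns `trial`, `channel`, then one column
#' per sample, microvolts) plus `<path>.json` (sampling rate, channel list,
#' trial layout) — a lossless plain-text interchange format.
#'
#' @param trials An `eeg_trials` object.
#' @param path Base path without extension.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(trials, path) {
  stopifnot(inherits(trials, "eeg_trials"))
  d <- dim(trials$data)
  flat <- matrix(aperm(trials$data, c(2, 1, 3)), nrow = d[1] * d[2])
  colnames(flat) <- sprintf("s%d", seq_len(d[3]))
  df <- tibble::as_tibble(as.data.frame(flat))
  df <- tibble::add_column(
    df,
    trial = rep(seq_len(d[1]), each = d[2]),
    channel = rep(trials$channel_names, d[1]),
    .before = 1
  )
  readr::write_csv(df, paste0(path, ".csv"), progress = FALSE)
  meta <- list(
    sampling_rate = trials$sampling_rate,
    channel_names = trials$channel_names,
    n_trials = d[1],
    n_samples = d[3],
    rest_duration = trials$paradigm$rest_duration %||% NULL,
    mi_duration = trials$paradigm$mi_duration %||% NULL,
    seed = trials$seed %||% NULL
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial-set archive
#'
#' Validates the sidecar, requires the full 11-channel canonical montage
#' (an error names any absent labels), normalizes channel order to the
#' canonical listing, refuses rate mismatches rather than resampling, and
#' drops incomplete (truncated) trials with a message.
#'
#' @param path Base path without extension (as written by
#'   [write_trialset()]).
#' @param expect_rate Optional required sampling rate in Hz; a mismatch is an
#'   error (resampling is refused, not attempted).
#' @param channels Required channel labels (default: the canonical 11).
#' @return An `eeg_trials` object.
#' @export
read_trialset <- function(path, expect_rate = NULL, channels = bci_channels()) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(expect_rate) && meta$sampling_rate != expect_rate) {
    abort(sprintf(
      "sampling rate is %g Hz but %g Hz is required; resampling is not supported",
      meta$sampling_rate, expect_rate
    ))
  }
  df <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE,
                        progress = FALSE)
  have <- unique(df$channel)
  missing_ch <- setdiff(channels, have)
  if (length(missing_ch)) {
    abort(paste0("archive is missing required channels: ",
                 paste(missing_ch, collapse = ", ")))
  }
  df <- df[df$channel %in% channels, , drop = FALSE]
  sample_cols <- grepl("^s\\d+$", names(df))
  n_samples <- sum(sample_cols)

  complete <- !apply(is.na(df[, sample_cols, drop = FALSE]), 1, any)
  bad_trials <- unique(df$trial[!complete])
  if (length(bad_trials)) {
    inform(sprintf("dropped %d incomplete trial(s)", length(bad_trials)))
    df <- df[!df$trial %in% bad_trials, , drop = FALSE]
  }
  trials_kept <- sort(unique(df$trial))
  nt <- length(trials_kept)
  if (nt == 0) abort("no complete trials in archive")

  data <- array(0, dim = c(nt, length(channels), n_samples))
  mat <- as.matrix(df[, sample_cols, drop = FALSE])
  for (i in seq_len(nt)) {
    rows <- df$trial == trials_kept[i]
    # normalize to canonical order regardless of file order
    ord <- match(channels, df$channel[rows])
    data[i, , ] <- mat[which(rows)[ord], , drop = FALSE]
  }
  as_eeg_trials(data, meta$sampling_rate, channels)
}

#' Serialize a fitted model to JSON
#'
#' Stores everything the online stage needs: per-band spatial filters and
#' eigenvalues, the feature mask, LDA weights and bias, the window and
#' filter-bank specifications, and the montage.
#'
#' @param model A `bci_model` from [fit_bci_model()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_bci_model <- function(model, path) {
  stopifnot(inherits(model, "bci_model"))
  payload <- list(
    sampling_rate = model$sampling_rate,
    channel_names = model$channel_names,
    band_edges = model$bank$band_edges,
    W = model$bank$W,
    eigenvalues = model$bank$eigenvalues,
    mask = model$mask,
    lda = list(
      weights = model$lda$weights,
      bias = model$lda$bias,
      feature_names = model$lda$feature_names,
      shrinkage_used = model$lda$shrinkage_used
    ),
    layout = unclass(model$layout),
    window_spec = unclass(model$window_spec),
    bank_spec = unclass(model$bank_spec)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path Path written by [write_bci_model()].
#' @return A `bci_model` object.
#' @export
read_bci_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # a homogeneous list of B matrices parses back as a B x n x n array
  split_first <- function(x) {
    if (is.list(x)) return(x)
    lapply(seq_len(dim(x)[1]), function(i) {
      if (length(dim(x)) == 3) x[i, , ] else x[i, ]
    })
  }
  band_edges <- if (is.matrix(p$band_edges)) {
    p$band_edges
  } else {
    do.call(rbind, p$band_edges)
  }
  bank <- structure(
    list(W = split_first(p$W),
         eigenvalues = split_first(p$eigenvalues),
         band_edges = band_edges,
         channel_names = p$channel_names),
    class = "csp_bank"
  )
  lda <- structure(
    list(weights = p$lda$weights, bias = p$lda$bias,
         levels = c("REST", "MI"),
         feature_names = p$lda$feature_names,
         shrinkage_used = p$lda$shrinkage_used),
    class = "bci_lda"
  )
  structure(
    list(bank = bank,
         mask = p$mask,
         lda = lda,
         layout = structure(p$layout, class = "feature_layout"),
         window_spec = window_spec(p$window_spec$rest_window,
                                   p$window_spec$mi_window),
         bank_spec = filter_bank_spec(
           bands = split_first(p$bank_spec$bands),
           filter_order = p$bank_spec$filter_order,
           notch = p$bank_spec$notch,
           notch_band = p$bank_spec$notch_band,
           transition = p$bank_spec$transition,
           trim_transient = p$bank_spec$trim_transient
         ),
         sampling_rate = p$sampling_rate,
         channel_names = p$channel_names),
    class = "bci_model"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised sections (`paradigm`, `erd`, `noise`, `windows`, `filter_bank`,
#' `pso`, `cv`, `online`) map one-to-one onto the corresponding constructor
#' arguments; omitted fields take the constructor defaults. A top-level
#' `seed` is carried through.
#'
#' @param path YAML file path.
#' @return Named list of specification objects plus `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(section, ctor) {
    args <- raw[[section]] %||% list()
    if (section == "filter_bank" && !is.null(args$bands)) {
      args$bands <- lapply(args$bands, unlist)
    }
    if (section == "erd" && !is.null(args$band)) args$band <- unlist(args$band)
    if (section == "windows") args <- lapply(args, unlist)
    do.call(ctor, args)
  }
  list(
    paradigm = build("paradigm", paradigm_spec),
    erd = if (is.null(raw$erd)) NULL else build("erd", erd_effect),
    noise = build("noise", noise_spec),
    windows = build("windows", window_spec),
    filter_bank = build("filter_bank", filter_bank_spec),
    pso = build("pso", pso_config),
    cv = build("cv", cv_scheme),
    online = build("online", online_protocol),
    seed = raw$seed %||% 1
  )
}

#' Write a run configuration to YAML
#'
#' Inverse of [read_run_config()]: the round trip reproduces every field.
#'
#' @param config List as returned by [read_run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  out <- list(
    paradigm = strip(config$paradigm),
    erd = strip(config$erd),
    noise = strip(config$noise),
    windows = strip(config$windows),
    filter_bank = strip(config$filter_bank),
    pso = strip(config$pso),
    cv = strip(config$cv),
    online = strip(config$online),
    seed = config$seed
  )
  out$paradigm$n_samples <- NULL # derived
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Hash of the configuration, the seed, package and R versions — enough to
#' re-run a command and reproduce its deterministic outputs.
#'
#' @param path Output `.json` path.
#' @param config Configuration list (see [read_run_config()]).
#' @param seed Integer seed used for the run.
#' @param outputs Optional character vector of output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs = NULL) {
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("fbcsp")),
    r_version = as.character(getRversion()),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
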