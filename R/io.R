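fmt_num <- function(x) sprintf("%.15g", x)

#' Read and write transient signals as delimited text
#'
#' The canonical on-disk form of one transient record: comma-separated
#' `time_s,signal` columns, an optional header row, and optional metadata as
#' leading `# key: value` comment lines (e.g. detection wavelength, site
#' label). A write/read round trip preserves values to at least 12
#' significant digits.
#'
#' @param path File path.
#' @param sig A data frame with numeric columns `time_s` and `signal`.
#' @param metadata Optional named list written as comment lines.
#' @return `read_signal()` returns a tibble with columns `time_s` and
#'   `signal` and a `metadata` attribute; the time column is validated to
#'   be finite and strictly increasing, with format errors reported by file
#'   line number.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' t <- seq(0, 0.01, length.out = 64)
#' write_signal(data.frame(time_s = t,
#'                         signal = signal_homogeneous(t, 1, 1e-3)), f)
#' sig <- read_signal(f)
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop(sprintf("%s: empty signal file", path), call. = FALSE)
  }
  is_comment <- startsWith(trimws(lines), "#")
  metadata <- list()
  for (ln in lines[is_comment]) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      metadata[[key]] <- val
    }
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(data_idx)) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  first <- strsplit(lines[data_idx[1]], ",")[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(trimws(first[1]))))
  row_idx <- if (has_header) data_idx[-1] else data_idx
  if (!length(row_idx)) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  parts <- strsplit(lines[row_idx], ",")
  bad_cols <- which(lengths(parts) < 2)
  if (length(bad_cols)) {
    stop(sprintf("%s: line %d: expected two comma-separated columns",
                 path, row_idx[bad_cols[1]]), call. = FALSE)
  }
  tvals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 1))))
  svals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 2))))
  bad <- which(is.na(tvals) | is.na(svals) | !is.finite(tvals) |
                 !is.finite(svals))
  if (length(bad)) {
    stop(sprintf("%s: line %d: non-numeric or non-finite cell",
                 path, row_idx[bad[1]]), call. = FALSE)
  }
  nonmono <- which(diff(tvals) <= 0)
  if (length(nonmono)) {
    stop(sprintf("%s: line %d: time column not strictly increasing",
                 path, row_idx[nonmono[1] + 1]), call. = FALSE)
  }
  out <- tibble::tibble(time_s = tvals, signal = svals)
  attr(out, "metadata") <- metadata
  out
}

#' @rdname read_signal
#' @export
write_signal <- function(sig, path, metadata = NULL) {
  sig <- as_signal_tbl(sig)
  check_time_grid(sig$time_s)
  lines <- character(0)
  if (length(metadata)) {
    lines <- sprintf("# %s: %s", names(metadata),
                     vapply(metadata, as.character, ""))
  }
  lines <- c(lines, "time_s,signal",
             paste(fmt_num(sig$time_s), fmt_num(sig$signal), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out[!vapply(out, is.null, logical(1))]
}

#' Write a dataset to a directory of delimited-text files
#'
#' Lays a dataset down as three plain-text files: `signals.csv` (first
#' column the shared time grid, one further column per signal),
#' `manifest.csv` (one row per signal: labels and, for synthetic data, the
#' generating truth parameters), and `dataset.yaml` (the fully resolved
#' generation spec, acquisition settings, seed, and package version).
#' [read_dataset()] reconstructs the dataset losslessly to 12 significant
#' digits.
#'
#' @param data An `otter_dataset`.
#' @param dir Target directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the reconstructed `otter_dataset`.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "otter_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(data$signals)
  ids <- rownames(data$signals)

  sig_tab <- cbind(fmt_num(data$grid),
                   matrix(fmt_num(t(data$signals)), ncol = n))
  lines <- c(paste(c("time_s", ids), collapse = ","),
             apply(sig_tab, 1, paste, collapse = ","))
  writeLines(lines, file.path(dir, "signals.csv"))

  truth <- data$truth
  names(truth) <- paste0("truth_", names(truth))
  manifest <- dplyr::bind_cols(tibble::tibble(id = ids), data$labels, truth)
  utils::write.csv(as.data.frame(manifest),
                   file.path(dir, "manifest.csv"), row.names = FALSE)

  meta <- list(kind = data$kind, seed = data$seed,
               package_version = as.character(utils::packageVersion("otter")),
               label_columns = names(data$labels),
               spec = spec_to_list(data$spec),
               acquisition = spec_to_list(data$acq))
  yaml::write_yaml(meta, file.path(dir, "dataset.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "dataset.yaml")
  if (!file.exists(meta_path)) {
    stop(sprintf("%s: not a dataset directory (no dataset.yaml)", dir),
         call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  sig <- utils::read.csv(file.path(dir, "signals.csv"),
                         check.names = FALSE)
  grid <- sig$time_s
  signals <- t(as.matrix(sig[, -1, drop = FALSE]))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              check.names = FALSE)
  label_cols <- meta$label_columns
  labels <- tibble::as_tibble(manifest[, label_cols, drop = FALSE])
  truth_cols <- grep("^truth_", names(manifest), value = TRUE)
  truth <- tibble::as_tibble(manifest[, truth_cols, drop = FALSE])
  names(truth) <- sub("^truth_", "", names(truth))
  if (meta$kind == "classification") {
    labels[[1]] <- factor(labels[[1]])
    if ("subject" %in% names(truth)) truth$subject <- factor(truth$subject)
    spec <- do.call(classification_spec,
                    meta$spec[names(meta$spec) %in%
                                names(formals(classification_spec))])
  } else {
    spec <- do.call(regression_spec,
                    meta$spec[names(meta$spec) %in%
                                names(formals(regression_spec))])
  }
  acq <- do.call(acquisition_config,
                 meta$acquisition[names(meta$acquisition) %in%
                                    names(formals(acquisition_config))])
  new_otter_dataset(signals, grid, labels, truth, kind = meta$kind,
                    spec = spec, acq = acq, seed = meta$seed)
}

#' Export a depth profile as delimited text
#'
#' Columns `z_um`, `beta_per_m`, and (when present) `hydration`.
#'
#' @param profile An `otter_depth_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  out <- data.frame(z_um = df$z_um, beta_per_m = df$beta)
  if ("hydration" %in% names(df)) out$hydration <- df$hydration
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline run configuration
#'
#' The fully resolved configuration consumed by [otter_cli()]: seed,
#' acquisition settings, physical constants, generation specs for the
#' regression and classification campaigns, the train/test split, model
#' registries, and SLS settings. [read_run_config()] reads a YAML file,
#' rejects unknown keys (reported with their field path), and fills
#' unspecified fields from these defaults.
#'
#' @return A nested named list.
#' @export
default_run_config <- function() {
  opt <- skin_defaults()
  list(
    seed = 1L,
    acquisition = list(n_points = 512L, t_max_over_tau = 20,
                       noise_sd = 0.01, baseline = 0),
    optics = list(D = opt$D, beta_w = opt$beta_w, beta_d = opt$beta_d),
    regression = list(n_signals = 97L, hydration_range = c(0.3, 0.9),
                      mode = "homogeneous",
                      gradient_range = c(-2e3, 2e3),
                      amplitude_mean = 1, amplitude_sd = 0.05),
    classification = list(n_classes = 4L, per_class = 5L,
                          class_hydration = c(0.35, 0.5, 0.65, 0.8),
                          class_amplitude = c(0.9, 1.0, 1.1, 1.2),
                          hydration_sd = 0.02, amplitude_sd = 0.02),
    split = list(train_fraction = 0.75, stratify = TRUE),
    models = list(regression = regression_models(),
                  classification = classification_models()),
    sls = list(n_slices = 10L, floor_frac = 0.02)
  )
}

check_config_keys <- function(cfg, template, path = character(0)) {
  for (nm in names(cfg)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(template)) {
      stop(sprintf("unknown configuration key: %s", here), call. = FALSE)
    }
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        length(names(template[[nm]]))) {
      if (!is.list(cfg[[nm]])) {
        stop(sprintf("configuration key %s must be a mapping", here),
             call. = FALSE)
      }
      check_config_keys(cfg[[nm]], template[[nm]], c(path, nm))
    }
  }
  invisible(TRUE)
}

merge_config <- function(cfg, template) {
  for (nm in names(template)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- template[[nm]]
    } else if (is.list(template[[nm]]) && length(names(template[[nm]]))) {
      cfg[[nm]] <- merge_config(cfg[[nm]], template[[nm]])
    }
  }
  cfg
}

#' @rdname default_run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  template <- default_run_config()
  check_config_keys(cfg, template)
  merge_config(cfg, template)
}
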