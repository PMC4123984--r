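# Tabular file dialects. All files are UTF-8, tab-separated, with optional
# `# key=value` metadata lines before the header.

read_meta_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  meta
}

# Linear interpolation of NA runs of length <= max_gap per column; longer
# runs leave NAs in place (caller decides the trial is invalid).
fill_short_gaps <- function(x, max_gap = 3L) {
  if (!anyNA(x)) return(list(x = x, filled = 0L, long_gap = FALSE))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- FALSE
  filled <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    len <- r$lengths[i]
    if (len > max_gap || starts[i] == 1L || ends[i] == length(x)) {
      long <- TRUE
      next
    }
    lo <- starts[i] - 1L; hi <- ends[i] + 1L
    x[starts[i]:ends[i]] <- x[lo] +
      (x[hi] - x[lo]) * (seq_len(len)) / (hi - lo)
    filled <- filled + len
  }
  list(x = x, filled = filled, long_gap = long)
}

#' Read a marker recording from a tabular file
#'
#' The tabular dialect is tab-separated UTF-8 with a header
#' `time<TAB><label>_x<TAB><label>_y<TAB><label>_z...`, one sample per row,
#' and optional metadata lines prefixed `#` (`# rate_hz=30`, `# side=left`,
#' `# system=lowcost`, `# session=id`). Gaps (empty or NA cells) of at most
#' 3 consecutive samples are linearly interpolated with a warning; longer
#' gaps invalidate the trial.
#'
#' @param path file path.
#' @param dialect `"tabular"` (canonical) or `"c3d"` (not available in this
#'   build; raises an informative error).
#' @param max_gap longest marker gap, in samples, that is repaired by linear
#'   interpolation.
#' @return a [marker_recording()].
#' @export
read_marker_file <- function(path, dialect = c("tabular", "c3d"), max_gap = 3L) {
  dialect <- match.arg(dialect)
  if (dialect == "c3d") {
    stop("C3D reading is not available in this build; convert to the tabular dialect")
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- read_meta_lines(lines)
  body <- grep("^#", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) < 1) stop(sprintf("no header row found in %s", path))
  hdr_line <- body[1]
  hdr <- strsplit(lines[hdr_line], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 4 || hdr[1] != "time") {
    stop(sprintf("malformed header at line %d of %s: expected 'time' then <label>_x/_y/_z columns",
                 hdr_line, path))
  }
  coord_cols <- hdr[-1]
  if (length(coord_cols) %% 3 != 0) {
    stop(sprintf("malformed header at line %d of %s: coordinate columns not in x/y/z triplets",
                 hdr_line, path))
  }
  labels <- character(0)
  for (i in seq(1, length(coord_cols), by = 3)) {
    trip <- coord_cols[i:(i + 2)]
    base <- sub("_[xyz]$", "", trip)
    sfx <- sub("^.*_", "", trip)
    if (!identical(sfx, c("x", "y", "z")) || length(unique(base)) != 1) {
      stop(sprintf("malformed header at line %d of %s: columns '%s' are not a <label>_x/_y/_z triplet",
                   hdr_line, path, paste(trip, collapse = ", ")))
    }
    labels <- c(labels, base[1])
  }
  dat <- utils::read.table(text = lines[body[-1]], sep = "\t",
                           header = FALSE, na.strings = c("NA", ""),
                           colClasses = "numeric")
  if (ncol(dat) != length(hdr)) {
    stop(sprintf("data rows of %s do not match header column count", path))
  }
  time <- dat[[1]]
  if (any(diff(time) <= 0)) stop(sprintf("non-monotonic timestamps in %s", path))
  pos <- unname(as.matrix(dat[-1]))
  filled_total <- 0L
  for (j in seq_len(ncol(pos))) {
    g <- fill_short_gaps(pos[, j], max_gap)
    if (g$long_gap) {
      stop(sprintf("marker gap longer than %d samples in column '%s' of %s: trial invalid",
                   max_gap, coord_cols[j], path))
    }
    pos[, j] <- g$x
    filled_total <- filled_total + g$filled
  }
  if (filled_total > 0) {
    warning(sprintf("interpolated %d gap sample(s) in %s", filled_total, path))
  }
  rate <- if (!is.null(meta$rate_hz)) as.numeric(meta$rate_hz) else NULL
  marker_recording(
    time = time, positions = pos, labels = labels, sample_rate = rate,
    limb_side = if (!is.null(meta$side)) meta$side else "left",
    system_tag = if (!is.null(meta$system)) meta$system else "standard",
    session_id = if (!is.null(meta$session)) meta$session else basename(path)
  )
}

#' Write a marker recording in the tabular dialect
#' @param rec a [marker_recording()].
#' @param path output file path.
#' @export
write_marker_file <- function(rec, path) {
  hdr <- c("time", as.vector(t(outer(rec$labels, c("x", "y", "z"),
                                     function(a, b) paste(a, b, sep = "_")))))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate_hz=%.10g", rec$sample_rate),
    sprintf("# side=%s", rec$limb_side),
    sprintf("# system=%s", rec$system_tag),
    sprintf("# session=%s", rec$session_id),
    paste(hdr, collapse = "\t")
  ), con)
  write_numeric_rows(cbind(rec$time, rec$positions), con)
  invisible(path)
}

# Full-precision (%.17g) tab-separated numeric rows, so write-then-read
# round-trips are bit-exact.
write_numeric_rows <- function(m, con) {
  txt <- apply(matrix(sprintf("%.17g", m), nrow(m)), 1, paste, collapse = "\t")
  writeLines(txt, con)
}

#' Read a joint-angle series from the tabular dialect
#'
#' Header `time<TAB>shoulder_flexext<TAB>shoulder_abdadd<TAB>elbow_flexext<TAB>wrist_flexext`
#' plus `#` metadata lines.
#' @param path file path.
#' @return a [joint_angle_series()].
#' @export
read_angle_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- read_meta_lines(lines)
  body <- grep("^#", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  hdr <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  expect <- c("time", angle_channels())
  if (!identical(hdr, expect)) {
    stop(sprintf("malformed angle-file header at line %d of %s (expected: %s)",
                 body[1], path, paste(expect, collapse = ", ")))
  }
  dat <- utils::read.table(text = lines[body[-1]], sep = "\t", header = FALSE,
                           colClasses = "numeric")
  time <- dat[[1]]
  if (any(diff(time) <= 0)) stop(sprintf("non-monotonic timestamps in %s", path))
  rate <- if (!is.null(meta$rate_hz)) as.numeric(meta$rate_hz)
          else 1 / stats::median(diff(time))
  joint_angle_series(unname(as.matrix(dat[-1])), sample_rate = rate,
                     limb_side = if (!is.null(meta$side)) meta$side else "left",
                     system_tag = if (!is.null(meta$system)) meta$system else "standard",
                     provenance = if (!is.null(meta$session)) meta$session else basename(path))
}

#' Write a joint-angle series in the tabular dialect
#' @param series a [joint_angle_series()].
#' @param path output file path.
#' @export
write_angle_file <- function(series, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate_hz=%.10g", series$sample_rate),
    sprintf("# side=%s", series$limb_side),
    sprintf("# system=%s", series$system_tag),
    sprintf("# session=%s", series$provenance),
    paste(c("time", angle_channels()), collapse = "\t")
  ), con)
  time <- (seq_len(nrow(series$angles)) - 1) / series$sample_rate
  write_numeric_rows(cbind(time, series$angles), con)
  invisible(path)
}

#' Read a movement template from the tabular dialect
#' @param path file path.
#' @export
read_template_file <- function(path) {
  s <- read_angle_file(path)
  lines <- readLines(path, warn = FALSE)
  meta <- read_meta_lines(lines)
  movement_template(s$angles,
                    movement_type = if (!is.null(meta$movement)) meta$movement else NA,
                    sample_rate = s$sample_rate)
}

#' Write a movement template in the tabular dialect
#' @param template a [movement_template()].
#' @param path output file path.
#' @export
write_template_file <- function(template, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rate_hz=%.10g", template$sample_rate),
    sprintf("# movement=%s", as.character(template$movement_type)),
    paste(c("time", angle_channels()), collapse = "\t")
  ), con)
  time <- (seq_len(nrow(template$traces)) - 1) / template$sample_rate
  write_numeric_rows(cbind(time, template$traces), con)
  invisible(path)
}

#' Read a rating panel
#'
#' Tab-separated with header `participant movement limb rater score`.
#' An empty file with only the header yields a valid empty panel.
#'
#' @param path file path.
#' @param scale_max maximal ordinal score (default 2).
#' @return a [rating_panel()].
#' @export
read_rating_panel <- function(path, scale_max = 2) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dat <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "character",
                                          "character", "numeric"),
                           comment.char = "#")
  needed <- c("participant", "movement", "limb", "rater", "score")
  if (!identical(names(dat), needed)) {
    stop(sprintf("malformed rating-panel header in %s (expected: %s)",
                 path, paste(needed, collapse = ", ")))
  }
  sc <- dat$score
  bad <- which(is.na(sc) | sc != round(sc) | sc < 0 | sc > scale_max)
  if (length(bad) > 0) {
    stop(sprintf("score outside {0..%d} at data row(s) %s of %s",
                 scale_max, paste(utils::head(bad, 5), collapse = ", "), path))
  }
  rating_panel(dat, scale_max = scale_max)
}

#' Write a rating panel
#' @param panel a [rating_panel()].
#' @param path output file path.
#' @export
write_rating_panel <- function(panel, path) {
  utils::write.table(panel$entries, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunables of the pipeline with their defaults: filter cutoff/order,
#' marker-gap policy, common trial length, segmentation threshold and
#' separation, PCA variance threshold and baseline mode, bootstrap settings,
#' and the repetition-bootstrap criterion.
#' @return named list.
#' @export
default_config <- function() {
  list(
    filter_cutoff_hz = 6,
    filter_order = 2,
    max_gap_samples = 3,
    max_degenerate_fraction = 0.10,
    common_length = 100,
    min_corr = 0.7,
    min_separation = 0.5,
    variance_threshold = 0.95,
    r2_pooling = "pooled",          # or "per_channel"
    baseline_mode = "include_all",  # or "leave_one_out"
    bootstrap_draws = 1000,
    bootstrap_alpha = 0.05,
    rep_criterion = "half-width",   # or "lower-bound"
    loso_level = "movement"         # or "participant"
  )
}

#' Read a YAML config file, merged over the defaults
#' @param path YAML file of key/value tunables; unknown keys are rejected.
#' @return named list as [default_config()].
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(cfg, user)
}
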