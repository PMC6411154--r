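# File dialects: tab-delimited UTF-8, '.' decimal separator, one header row.
# Every reader error names the file and, where meaningful, the line number.

EXPRESSION_HEADER <- c("region", "group", "animal", "value")
CONNECTOME_HEADER <- c("source", "target", "weight")

read_lines_checked <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  readLines(path, encoding = "UTF-8")
}

parse_number <- function(x, path, line_no, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stopf("%s: line %d: non-numeric %s '%s'", path, line_no[bad[1]], what,
          x[bad[1]])
  }
  v
}

split_tsv <- function(lines, path, n_fields) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad)) {
    stopf("%s: line %d: expected %d tab-separated fields, found %d",
          path, bad[1] + 1L, n_fields, lengths(parts)[bad[1]])
  }
  parts
}

#' Read / write an expression table
#'
#' Tab-delimited with header `region	group	animal	value`. Values must be
#' numeric and non-negative; duplicate (region, group, animal) keys are
#' rejected. Errors name the offending line.
#'
#' @param path File path.
#' @return `read_expression()`: a validated data.frame;
#'   `write_expression()`: the path, invisibly.
#' @export
read_expression <- function(path) {
  lines <- read_lines_checked(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]],
                                   EXPRESSION_HEADER)) {
    stopf("%s: malformed header (expected '%s')", path,
          paste(EXPRESSION_HEADER, collapse = "\\t"))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(data.frame(region = character(), group = character(),
                      animal = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- split_tsv(body, path, 4L)
  m <- do.call(rbind, parts)
  line_no <- seq_along(body) + 1L
  value <- parse_number(m[, 4], path, line_no, "value")
  neg <- which(value < 0)
  if (length(neg)) {
    stopf("%s: line %d: negative expression value %g", path, line_no[neg[1]],
          value[neg[1]])
  }
  key <- paste(m[, 1], m[, 2], m[, 3], sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("%s: line %d: duplicate (region, group, animal) record", path,
          line_no[dup[1]])
  }
  data.frame(region = m[, 1], group = m[, 2], animal = m[, 3], value = value,
             stringsAsFactors = FALSE)
}

#' @rdname read_expression
#' @param x Expression data.frame (`region`, `group`, `animal`, `value`).
#' @export
write_expression <- function(x, path) {
  stopifnot(all(EXPRESSION_HEADER %in% names(x)))
  write_tsv(x[, EXPRESSION_HEADER], path)
}

#' Read / write a connectome edge list
#'
#' Tab-delimited with header `source	target	weight`. Weights must be
#' positive; self-edges and duplicate ordered pairs are rejected. Errors
#' name the offending line.
#'
#' @param path File path.
#' @return `read_connectome()`: a validated `connectome`;
#'   `write_connectome()`: the path, invisibly.
#' @export
read_connectome <- function(path) {
  lines <- read_lines_checked(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]],
                                   CONNECTOME_HEADER)) {
    stopf("%s: malformed header (expected '%s')", path,
          paste(CONNECTOME_HEADER, collapse = "\\t"))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) stopf("%s: no edges", path)
  parts <- split_tsv(body, path, 3L)
  m <- do.call(rbind, parts)
  line_no <- seq_along(body) + 1L
  weight <- parse_number(m[, 3], path, line_no, "weight")
  bad <- which(weight <= 0)
  if (length(bad)) {
    stopf("%s: line %d: non-positive weight %g", path, line_no[bad[1]],
          weight[bad[1]])
  }
  self <- which(m[, 1] == m[, 2])
  if (length(self)) {
    stopf("%s: line %d: self-edge '%s'", path, line_no[self[1]], m[self[1], 1])
  }
  key <- paste(m[, 1], m[, 2], sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("%s: line %d: duplicate edge %s -> %s", path, line_no[dup[1]],
          m[dup[1], 1], m[dup[1], 2])
  }
  as_connectome(data.frame(source = m[, 1], target = m[, 2], weight = weight,
                           stringsAsFactors = FALSE))
}

#' @rdname read_connectome
#' @param x Connectome (or data.frame with `source`, `target`, `weight`).
#' @export
write_connectome <- function(x, path) {
  stopifnot(all(CONNECTOME_HEADER %in% names(x)))
  write_tsv(as.data.frame(x)[, CONNECTOME_HEADER], path)
}

#' Read / write a trace matrix
#'
#' One delimited matrix per session: first column `time` (seconds), one
#' column per unit, header row of unit IDs.
#'
#' @param path File path.
#' @return `read_traces()`: list with `traces` (matrix, one column per
#'   unit), `time`, and `fps` inferred from the time column;
#'   `write_traces()`: the path, invisibly.
#' @export
read_traces <- function(path) {
  lines <- read_lines_checked(path)
  if (!length(lines)) stopf("%s: empty file", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "time" || length(header) < 2L) {
    stopf("%s: malformed header (expected 'time' then unit IDs)", path)
  }
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  if (any(!vapply(df, is.numeric, logical(1)))) {
    stopf("%s: non-numeric entries in trace matrix", path)
  }
  time <- df[[1]]
  if (length(time) < 2L) stopf("%s: need >= 2 samples", path)
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stopf("%s: time column must be strictly increasing and evenly spaced",
          path)
  }
  traces <- as.matrix(df[, -1, drop = FALSE])
  list(traces = traces, time = time, fps = 1 / mean(dt))
}

#' @rdname read_traces
#' @param traces Matrix, one column per unit.
#' @param time Sample times in seconds (length `nrow(traces)`).
#' @export
write_traces <- function(traces, time, path) {
  stopifnot(is.matrix(traces), length(time) == nrow(traces))
  units <- colnames(traces)
  if (is.null(units)) units <- paste0("unit", seq_len(ncol(traces)))
  df <- data.frame(time = time, traces, check.names = FALSE)
  names(df) <- c("time", units)
  write_tsv(df, path)
}

#' Write a node-score table
#'
#' One row per region with the phi / phi_con scores, their drug-minus-saline
#' differences, and per-score ranks, as produced by
#' [cfos_network_scores()].
#'
#' @param scores Node-score data.frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_node_scores <- function(scores, path) {
  cols <- c("region", "phi_saline", "phi_drug", "delta_phi",
            "phicon_out_saline", "phicon_out_drug", "delta_phicon_out",
            "phicon_in_saline", "phicon_in_drug", "delta_phicon_in",
            "rank_delta_phi", "rank_delta_phicon_out",
            "rank_delta_phicon_in")
  stopifnot(all(cols %in% names(scores)))
  write_tsv(scores[, cols], path)
}

#' Write detected events
#'
#' @param events Event data.frame with `unit` and `session` columns (see
#'   [calcium_event_analysis()]).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("unit", "session", "onset_s", "amplitude", "tau_s")
  stopifnot(all(cols %in% names(events)))
  write_tsv(events[, cols], path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# --- run configuration -------------------------------------------------------

run_config_defaults <- function() {
  list(
    expression_file = NA_character_,
    connectome_file = NA_character_,
    traces_saline_file = NA_character_,
    traces_drug_file = NA_character_,
    drug_label = "DZP",
    saline_label = "saline",
    homecage_label = "homecage",
    conditions = "none,EPM,shock,shock_EPM",
    zscore_scope = "crossed",
    rank_by = "absolute",
    fps = 20,
    cutoff_hz = 2,
    threshold_sd = 6,
    min_tau_s = 0.5,
    release_sd = 2,
    f0_probs = 0.1,
    seed = 1,
    out_dir = ".",
    log_level = "info"
  )
}

#' Load a flat key-value run configuration
#'
#' One `key: value` pair per line (`#` comments and blank lines ignored).
#' Unknown keys are rejected; missing keys fall back to documented
#' defaults; numeric tunables are range-checked (e.g. `threshold_sd > 0`,
#' `0 < cutoff_hz < fps / 2`).
#'
#' @param path File path, or `NULL` for pure defaults.
#' @return Named list of resolved settings.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    lines <- read_lines_checked(path)
    for (i in seq_along(lines)) {
      line <- sub("#.*$", "", lines[i])
      if (!nzchar(trimws(line))) next
      if (!grepl(":", line, fixed = TRUE)) {
        stopf("%s: line %d: expected 'key: value'", path, i)
      }
      key <- trimws(sub(":.*$", "", line))
      value <- trimws(sub("^[^:]*:", "", line))
      if (!key %in% names(cfg)) stopf("%s: line %d: unknown key '%s'",
                                      path, i, key)
      cfg[[key]] <- if (is.numeric(cfg[[key]])) {
        v <- suppressWarnings(as.numeric(value))
        if (is.na(v)) stopf("%s: line %d: non-numeric value for '%s'",
                            path, i, key)
        v
      } else value
    }
  }
  check_scalar_number(cfg$fps, "fps", lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$threshold_sd, "threshold_sd", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(cfg$min_tau_s, "min_tau_s", lower = 0)
  check_scalar_number(cfg$release_sd, "release_sd", lower = 0)
  check_scalar_number(cfg$f0_probs, "f0_probs", lower = 0, upper = 1)
  if (!(cfg$cutoff_hz > 0 && cfg$cutoff_hz < cfg$fps / 2)) {
    stopf("`cutoff_hz` must lie in (0, fps/2) = (0, %g)", cfg$fps / 2)
  }
  if (!cfg$zscore_scope %in% c("crossed", "all")) {
    stopf("`zscore_scope` must be 'crossed' or 'all'")
  }
  if (!cfg$rank_by %in% c("absolute", "signed")) {
    stopf("`rank_by` must be 'absolute' or 'signed'")
  }
  cfg$conditions_vec <- strsplit(cfg$conditions, ",", fixed = TRUE)[[1]]
  cfg
}
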