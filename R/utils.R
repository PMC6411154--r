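# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed) || abs(seed) >= 2^31) {
    stop("`seed` must be a single integer with |seed| < 2^31", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stopf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  }
  invisible(x)
}

#' Crossed treatment-group label
#'
#' Builds the group label for a drug state crossed with an anxiety condition.
#' The no-anxiety condition (`"none"`) maps to the bare state label, so the
#' eight crossed groups read e.g. `saline`, `saline_EPM`, `saline_shock`,
#' `saline_shock_EPM`, `DZP`, `DZP_EPM`, ...
#'
#' @param state Drug-state label (e.g. `"saline"` or `"DZP"`).
#' @param condition Anxiety-condition label; `"none"` means no stressor.
#' @param sep Separator between state and condition.
#' @return Character vector of group labels.
#' @export
#' @examples
#' group_label("DZP", c("none", "EPM", "shock", "shock_EPM"))
group_label <- function(state, condition, sep = "_") {
  ifelse(condition == "none", state, paste(state, condition, sep = sep))
}

#' Default limbic region labels
#'
#' The 15 limbic regions commonly profiled in c-Fos mapping of anxiolytic
#' drug action, used as fixture defaults by the synthetic generators. Any
#' other label set is equally valid throughout the package.
#'
#' @return Character vector of 15 region acronyms.
#' @export
limbic_regions <- function() {
  c("ACAd", "ACAv", "AI", "BLA", "BST", "CEA", "ILA", "LA",
    "LSc", "LSr", "LSv", "PAG", "PL", "PVH", "PVT")
}

# Population standard deviation (divide by N, not N - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
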