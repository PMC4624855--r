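#' @title Descriptor correlation and equilibration diagnostics
#' @description Pearson correlation of network-descriptor time series
#'   (including time itself) and the equilibration criterion built on it: a
#'   trajectory at a relative conformational minimum shows no significant
#'   correlation of its descriptors with time.
#' @name ensemble-stats
NULL

#' Pearson correlation matrix of descriptor series
#'
#' Correlates every pair among time and the descriptor columns. P-values
#' come from the two-sided t-test with n - 2 degrees of freedom. Constant
#' series yield an undefined correlation, reported as `NA` and flagged.
#' Frames are assumed far enough apart (e.g. 10 ps) that autocorrelation is
#' ignored; treat p-values on strongly autocorrelated series with care.
#'
#' @param descriptors data frame with a time column and descriptor columns,
#'   as from [descriptor_series()]
#' @param vars descriptor columns to use (defaults to the standard four,
#'   intersected with what is present)
#' @param time_col name of the time column
#' @return a `pcn_corr` object: `variables`, `r`, `p` (matrices), `n`,
#'   `constant` flags
#' @export
correlation_matrix <- function(descriptors,
                               vars = c("adeg", "asp", "graph_energy",
                                        "dG_solv"),
                               time_col = "time_ps") {
  descriptors <- as.data.frame(descriptors)
  vars <- intersect(vars, names(descriptors))
  vars <- vars[vapply(descriptors[vars], function(v) !all(is.na(v)), TRUE)]
  if (!time_col %in% names(descriptors))
    rlang::abort(sprintf("no time column '%s'", time_col),
                 class = "pcnmd_schema_error")
  cols <- c(t = time_col, setNames(vars, vars))
  x <- descriptors[, cols, drop = FALSE]
  names(x) <- names(cols)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 4)
    rlang::abort("need at least 4 complete frames",
                 class = "pcnmd_insufficient_data")
  m <- length(cols)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(names(cols), names(cols)))
  diag(r) <- 1
  constant <- vapply(x, function(v) stats::sd(v) == 0, TRUE)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (constant[i] || constant[j]) next
      ct <- cor.test(x[[i]], x[[j]], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(variables = names(cols), r = r, p = p, n = n,
                 constant = constant),
            class = "pcn_corr")
}

#' @export
print.pcn_corr <- function(x, digits = 2, ...) {
  cat(sprintf("<pcn_corr> Pearson correlations over %d frames\n", x$n))
  shown <- format(round(x$r, digits))
  shown[lower.tri(shown, diag = TRUE)] <- ""
  print(shown, quote = FALSE)
  if (any(x$constant))
    cat("constant series (r undefined):",
        paste(x$variables[x$constant], collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn correlation_matrix long table of the unique pairs:
#'   `var1`, `var2`, `r`, `p`
#' @param x a `pcn_corr`
#' @param ... unused
#' @method tidy pcn_corr
#' @export
tidy.pcn_corr <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(var1 = x$variables[idx[, 1]], var2 = x$variables[idx[, 2]],
                 r = x$r[idx], p = x$p[idx])
}

#' Equilibration verdict from descriptor-time correlations
#'
#' A descriptor is `drifting` iff its correlation with time is significant
#' (`p < alpha`); otherwise `stationary`. An undefined correlation (constant
#' series) counts as no evidence of drift. The verdict is reported alongside
#' raw r and p, never as a bare label: the convention is that a trajectory
#' at its conformational minimum shows non-significant descriptor-time
#' correlations.
#'
#' @param report a `pcn_corr` from [correlation_matrix()]
#' @param alpha significance level (default 0.05)
#' @return tibble with columns `variable`, `r`, `p`, `verdict`
#' @export
equilibration_check <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "pcn_corr"), alpha > 0, alpha < 1)
  vars <- setdiff(report$variables, "t")
  r <- report$r["t", vars]
  p <- report$p["t", vars]
  tibble::tibble(variable = vars, r = unname(r), p = unname(p),
                 verdict = ifelse(!is.na(p) & p < alpha,
                                  "drifting", "stationary"),
                 alpha = alpha)
}
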