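#' Conditional independence tests for categorical data
#'
#' `ci_test_g2()` computes the likelihood-ratio (G-squared) test of
#' `x` independent of `y` given the conditioning set `S`, stratifying the
#' contingency table by every configuration of `S`. Degrees of freedom are
#' accumulated per stratum from the observed positive margins, so empty
#' categories and empty strata do not inflate the reference distribution;
#' if no stratum retains positive degrees of freedom the test is
#' undecidable and reported as independence (`p = 1`, `dof = 0`).
#'
#' @param ds a complete-case `genotype_dataset` with integer-coded columns.
#' @param x,y variable names, `x != y`.
#' @param S character vector of conditioning variable names (may be empty).
#' @return object of class `ci_test_result`: list with `statistic`, `dof`,
#'   `p_value` and `method`.
#' @examples
#' ds <- genotype_dataset(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
#'                               dimnames = list(NULL, c("a", "b"))))
#' ci_test_g2(ds, "a", "b")
#' @export
ci_test_g2 <- function(ds, x, y, S = character()) {
  codes <- ci_codes(ds, x, y, S)
  res <- g2_stat_cpp(codes$x, codes$y, codes$S, codes$cx, codes$cy, codes$cardS)
  stat <- res$statistic
  dof <- res$dof
  p <- if (dof <= 0) 1 else stats::pchisq(stat, dof, lower.tail = FALSE)
  structure(list(statistic = stat, dof = dof, p_value = p, method = "g2"),
            class = "ci_test_result")
}

# 0-based integer codes + cardinalities for a test
ci_codes <- function(ds, x, y, S) {
  if (x == y) stop("x and y must differ")
  if (x %in% S || y %in% S) stop("S must not contain x or y")
  vars <- c(x, y, S)
  miss <- setdiff(vars, ds$variables)
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  if (any(ds$missing_mask[, vars]))
    stop("CI tests require complete cases for the tested variables")
  v <- ds$values
  card <- ds$cardinalities[vars]
  if (anyNA(card))
    stop("variable(s) without integer coding: ",
         paste(vars[is.na(card)], collapse = ", "))
  list(x = as.integer(v[, x]), y = as.integer(v[, y]),
       S = matrix(as.integer(v[, S, drop = FALSE]), nrow = nrow(v)),
       cx = card[[x]], cy = card[[y]],
       cardS = as.integer(card[S]))
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("CI test (%s): statistic = %.4f, dof = %d, p = %.4g\n",
              x$method, x$statistic, as.integer(x$dof), x$p_value))
  invisible(x)
}

#' Symmetric two-response conditional independence test
#'
#' Treats each of `x` and `y` in turn as a categorical response: fits a
#' multinomial logistic regression of the response on `S` and on
#' `S` plus the other variable, performs the two likelihood-ratio tests, and
#' combines the two p-values — by default taking their maximum (a
#' conservative, symmetric rule), optionally by Fisher's method. A fit that
#' fails to converge falls back to [ci_test_g2()] with a warning.
#'
#' @inheritParams ci_test_g2
#' @param combine `"max"` or `"fisher"`.
#' @return a `ci_test_result`; `statistic` is the larger of the two LRT
#'   statistics and `dof` its degrees of freedom.
#' @export
ci_test_symmetric <- function(ds, x, y, S = character(),
                              combine = c("max", "fisher")) {
  combine <- match.arg(combine)
  ci_codes(ds, x, y, S)  # shared validation
  dat <- as.data.frame(lapply(as.data.frame(ds$values[, c(x, y, S),
                                                      drop = FALSE]), factor))
  names(dat) <- make.names(c(".x", ".y", if (length(S)) paste0(".s", seq_along(S))))
  one_lrt <- function(resp, other) {
    covs <- names(dat)[-(1:2)]
    rhs0 <- if (length(covs)) paste(covs, collapse = " + ") else "1"
    f0 <- stats::as.formula(paste(resp, "~", rhs0))
    f1 <- stats::as.formula(paste(resp, "~", rhs0, "+", other))
    m0 <- nnet::multinom(f0, data = dat, trace = FALSE, maxit = 200)
    m1 <- nnet::multinom(f1, data = dat, trace = FALSE, maxit = 200)
    stat <- max(m0$deviance - m1$deviance, 0)
    dof <- max(m1$edf - m0$edf, 1)
    list(stat = stat, dof = dof,
         p = stats::pchisq(stat, dof, lower.tail = FALSE))
  }
  res <- tryCatch({
    a <- one_lrt(".x", ".y")
    b <- one_lrt(".y", ".x")
    p <- switch(combine,
                max = max(a$p, b$p),
                fisher = stats::pchisq(-2 * (log(a$p) + log(b$p)), 4,
                                       lower.tail = FALSE))
    big <- if (a$stat >= b$stat) a else b
    structure(list(statistic = big$stat, dof = big$dof, p_value = p,
                   method = paste0("symmetric-", combine)),
              class = "ci_test_result")
  }, error = function(e) {
    warning("symmetric test failed (", conditionMessage(e),
            "); falling back to G2")
    ci_test_g2(ds, x, y, S)
  })
  res
}
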