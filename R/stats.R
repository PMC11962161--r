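# Two-sample tests used throughout the analyses: the nonparametric
# Brunner-Munzel test (relative effect with a studentized t reference) and
# Welch's two-tailed t-test.

#' Brunner-Munzel nonparametric two-sample test
#'
#' Tests H0: P(X < Y) + 0.5 P(X = Y) = 0.5 using midranks. The relative
#' effect is estimated from the combined-sample midranks; the studentized
#' statistic is referred to a t distribution with Satterthwaite-type degrees
#' of freedom (the standard small-sample recommendation). A permutation
#' variant is available for very small samples.
#'
#' @param x,y Numeric samples (each n >= 2; not both constant and equal).
#' @param method "t" (default) or "permutation".
#' @param n_perm Number of random label permutations for
#'   `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return Object of class `bm_test`: list(statistic, df, p_value,
#'   relative_effect, n_x, n_y, method).
#' @export
brunner_munzel <- function(x, y, method = c("t", "permutation"),
                           n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs >= 2 values", call. = FALSE)
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  r1i <- rank(x); r2i <- rank(y)
  v1 <- sum((r1 - r1i - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - r2i - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (v1 == 0 && v2 == 0) {
    if (isTRUE(all.equal(sort(x), sort(y))) || p_hat == 0.5) {
      stop("degenerate-variance error: both samples constant and equal",
           call. = FALSE)
    }
    # complete separation: effect 0 or 1 with zero variance
    return(structure(list(statistic = sign(p_hat - 0.5) * Inf, df = NA_real_,
                          p_value = 0, relative_effect = p_hat, n_x = n1,
                          n_y = n2, method = method), class = "bm_test"))
  }
  stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(n1 * v1 + n2 * v2)
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  if (method == "t") {
    p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  } else {
    set.seed(seed)
    z <- c(x, y)
    obs <- abs(p_hat - 0.5)
    eff <- replicate(n_perm, {
      idx <- sample.int(n1 + n2, n1)
      rp <- rank(z)
      abs((mean(rp[-idx]) - (n2 + 1) / 2) / n1 - 0.5)
    })
    p <- mean(eff >= obs - 1e-12)
  }
  structure(list(statistic = stat, df = df, p_value = min(p, 1),
                 relative_effect = p_hat, n_x = n1, n_y = n2,
                 method = method), class = "bm_test")
}

#' Welch two-tailed t-test
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE`, returned in
#' the same shape as [brunner_munzel()].
#'
#' @param x,y Numeric samples (n >= 2 per group, not both zero-variance).
#' @return Object of class `bm_test`: list(statistic, df, p_value, n_x,
#'   n_y).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(statistic = 0, df = NA_real_, p_value = 1,
                            relative_effect = NA_real_, n_x = length(x),
                            n_y = length(y), method = "welch"),
                       class = "bm_test"))
    }
    stop("degenerate-variance error: both samples have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, relative_effect = NA_real_,
                 n_x = length(x), n_y = length(y), method = "welch"),
            class = "bm_test")
}

#' @export
print.bm_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, df = %.3g, p = %.4g\n",
              if (x$method == "welch") "Welch t" else "Brunner-Munzel",
              x$statistic, x$df, x$p_value))
  if (!is.na(x$relative_effect)) {
    cat(sprintf("relative effect P(X<Y)+0.5P(X=Y) = %.4f (n = %d, %d)\n",
                x$relative_effect, x$n_x, x$n_y))
  }
  invisible(x)
}
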