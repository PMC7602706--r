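# Exact null distribution of the Mann-Whitney U statistic (no ties).
# U = u occurs in as many label arrangements as there are partitions of u
# into at most n1 parts, each part at most n2; standard recurrence
# P(i, j, u) = P(i, j-1, u) + P(i-1, j, u-j).
mw_exact_counts <- function(n1, n2) {
  umax <- n1 * n2
  P <- array(0, dim = c(n1 + 1, n2 + 1, umax + 1))
  P[, , 1] <- 1
  for (i in seq_len(n1))
    for (j in seq_len(n2))
      for (u in seq_len(umax)) {
        v <- P[i + 1, j, u + 1]
        if (u >= j) v <- v + P[i, j + 1, u - j + 1]
        P[i + 1, j + 1, u + 1] <- v
      }
  P[n1 + 1, n2 + 1, ]
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a difference between two independent samples.  For
#' `n1 + n2 <= 20` without ties the exact null distribution of U is used
#' (two-sided p = `2 * min(P(U <= u), P(U >= u))`, capped at 1); otherwise a
#' tie-corrected normal approximation with continuity correction is applied,
#' with a message when ties force the fallback.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; `NULL`
#'   (default) decides from sample sizes and ties.
#' @return object of class `mann_whitney_result`: list with `U` (statistic of
#'   sample `a`), `p_value`, `method` (`"exact"` or `"normal_approx"`),
#'   `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # exactly 0.1
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  if (!all(is.finite(c(a, b)))) stop("non-finite values in input")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- if (is.null(exact)) n1 + n2 <= 20L else exact
  if (use_exact && has_ties) {
    message("ties present: falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    cnt <- mw_exact_counts(n1, n2)
    tot <- sum(cnt)
    p_le <- sum(cnt[seq_len(U + 1)]) / tot
    p_ge <- sum(cnt[(U + 1):length(cnt)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      if (U == mu) z <- 0
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(U = U, p_value = p, method = method, n1 = n1, n2 = n2),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Per-channel group difference map
#'
#' Raw per-channel difference of group-level slope values
#' (`r_elderly - r_young`, signed) and its normalized version.  With
#' `normalize = "max"` (default) values are divided by the maximum absolute
#' difference so the strongest channel is +/-1; `"zscore"` centres and scales
#' instead.  An all-zero map stays all zero.
#'
#' @param r_elderly,r_young named numeric vectors of per-channel slope values
#'   over identical channel sets.
#' @param normalize `"max"` or `"zscore"`.
#' @return object of class `channel_difference_map`: data frame with columns
#'   `channel`, `raw`, `normalized`.
#' @export
channel_difference_map <- function(r_elderly, r_young,
                                   normalize = c("max", "zscore")) {
  normalize <- match.arg(normalize)
  if (is.null(names(r_elderly)) || is.null(names(r_young)))
    stop("per-channel values must be named by channel")
  if (!setequal(names(r_elderly), names(r_young)))
    stop("channel sets differ between groups")
  r_young <- r_young[names(r_elderly)]
  raw <- r_elderly - r_young
  normed <- if (normalize == "max") {
    m <- max(abs(raw))
    if (m > 0) raw / m else raw
  } else {
    s <- sd(raw)
    if (is.finite(s) && s > 0) (raw - mean(raw)) / s else raw * 0
  }
  out <- data.frame(channel = names(raw), raw = unname(raw),
                    normalized = unname(normed))
  class(out) <- c("channel_difference_map", "data.frame")
  out
}

#' Tabulated group comparison (slope table + tests)
#'
#' Assembles the full inter-group report: for every channel x segment x
#' hand-condition cell it gives each group's mean slope with its standard
#' error across subjects, the Mann-Whitney U and two-sided p-value, and a
#' significance flag at level `alpha`.
#'
#' @param slopes data frame of per-subject slopes with columns `group`,
#'   `subject`, `channel`, `segment`, `hand_condition`, `r`.  Exactly two
#'   group labels must be present.
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default, matching per-channel reporting) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values.
#' @return data frame with one row per cell: group means, SEs, subject
#'   counts, `U`, `p_value`, `significant`.
#' @export
compare_groups <- function(slopes, alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  slopes <- as.data.frame(slopes)
  need <- c("group", "subject", "channel", "segment", "hand_condition", "r")
  stopifnot(all(need %in% names(slopes)))
  groups <- sort(unique(as.character(slopes$group)))
  if (length(groups) != 2L) stop("exactly two groups are required")
  cells <- unique(slopes[c("channel", "segment", "hand_condition")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    sub <- slopes[slopes$channel == cl$channel & slopes$segment == cl$segment &
                  slopes$hand_condition == cl$hand_condition, ]
    ra <- sub$r[sub$group == groups[1]]
    rb <- sub$r[sub$group == groups[2]]
    mw <- if (length(ra) >= 2 && length(rb) >= 2) mann_whitney(ra, rb) else NULL
    out[[i]] <- data.frame(
      channel = cl$channel, segment = cl$segment,
      hand_condition = cl$hand_condition,
      mean_a = mean(ra), se_a = sd(ra) / sqrt(length(ra)), n_a = length(ra),
      mean_b = mean(rb), se_b = sd(rb) / sqrt(length(rb)), n_b = length(rb),
      U = if (is.null(mw)) NA_real_ else mw$U,
      p_value = if (is.null(mw)) NA_real_ else mw$p_value)
  }
  rep <- do.call(rbind, out)
  names(rep)[names(rep) == "mean_a"] <- paste0("mean_", groups[1])
  names(rep)[names(rep) == "se_a"] <- paste0("se_", groups[1])
  names(rep)[names(rep) == "n_a"] <- paste0("n_", groups[1])
  names(rep)[names(rep) == "mean_b"] <- paste0("mean_", groups[2])
  names(rep)[names(rep) == "se_b"] <- paste0("se_", groups[2])
  names(rep)[names(rep) == "n_b"] <- paste0("n_", groups[2])
  if (p_adjust == "BH") rep$p_value <- p.adjust(rep$p_value, "BH")
  rep$significant <- !is.na(rep$p_value) & rep$p_value < alpha
  attr(rep, "groups") <- groups
  attr(rep, "alpha") <- alpha
  rep
}
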