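#' Expected reference-read fraction under sequencing noise
#'
#' Maps a true reference-allele fraction p = d/K to the expected fraction of
#' reference reads after sequencing error and allelic bias:
#' f = p (1 - seq_error) + (1 - p) seq_error, then
#' xi = f / (bias (1 - f) + f). `bias = 1` is no bias; `bias < 1` makes the
#' reference allele over-detected. This one function is shared between the
#' read-count simulator and the noise-aware posterior estimator.
#'
#' @param p true reference-allele fraction in \[0, 1\].
#' @param bias allelic bias, > 0.
#' @param seq_error per-read sequencing error rate in \[0, 0.5).
#' @return Expected reference-read fraction(s) in \[0, 1\].
#' @export
ref_fraction_xi <- function(p, bias = 1, seq_error = 0.001) {
  stopifnot(bias > 0, seq_error >= 0, seq_error < 0.5)
  f <- p * (1 - seq_error) + (1 - p) * seq_error
  f / (bias * (1 - f) + f)
}

## log beta-binomial pmf parameterised by mean xi and overdispersion rho:
## alpha = xi (1 - rho) / rho, beta = (1 - xi)(1 - rho) / rho.
## rho = 0 degenerates to the binomial; xi in {0, 1} to a point mass.
## Vectorised over x/size (xi, rho scalars). Includes the choose() term.
dbetabinom_log <- function(x, size, xi, rho) {
  if (rho < 0 || rho >= 1) stop("overdispersion must be in [0, 1)")
  if (xi <= 0) return(ifelse(x == 0, 0, -Inf))
  if (xi >= 1) return(ifelse(x == size, 0, -Inf))
  if (rho == 0) return(dbinom(x, size, xi, log = TRUE))
  a <- xi * (1 - rho) / rho
  b <- (1 - xi) * (1 - rho) / rho
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

#' Noise-aware posterior dosage probabilities
#'
#' A segregation-prior beta-binomial posterior over allele dosages: for each
#' individual, posterior(d) is proportional to
#' prior(d) * BetaBinomial(RD | DP, xi(d/K), od), with xi from
#' [ref_fraction_xi]. The prior is typically the expected offspring dosage
#' distribution of the population ([offspring_dosage_distribution]), or
#' uniform when the population type is unknown. This is a deliberately
#' simple estimator that accounts for allelic bias and overdispersion;
#' it does not iterate over markers or share information between them.
#'
#' @param DP_vec,RD_vec integer vectors of total/reference depths over
#'   individuals (`NA` allowed, propagated as masked rows).
#' @param prior dosage prior, length ploidy + 1, summing to 1.
#' @param bias,od,seq_error noise parameters (allelic bias > 0,
#'   overdispersion in \[0, 1), sequencing error in \[0, 0.5)).
#' @return Matrix individuals x (ploidy + 1); unmasked rows sum to 1.
#' @export
noise_aware_posterior <- function(DP_vec, RD_vec, prior, bias = 1, od = 0,
                                  seq_error = 0.001) {
  stopifnot(length(DP_vec) == length(RD_vec),
            abs(sum(prior) - 1) < 1e-6)
  if (od < 0 || od >= 1) stop("overdispersion out of range [0, 1)")
  if (bias <= 0) stop("bias must be positive")
  K <- length(prior) - 1L
  n <- length(DP_vec)
  out <- matrix(NA_real_, n, K + 1,
                dimnames = list(names(DP_vec), as.character(0:K)))
  ok <- which(!is.na(DP_vec) & !is.na(RD_vec))
  if (!length(ok)) return(out)
  lp <- matrix(-Inf, length(ok), K + 1)
  for (d in 0:K) {
    if (prior[d + 1] <= 0) next
    xi <- ref_fraction_xi(d / K, bias, seq_error)
    lp[, d + 1] <- log(prior[d + 1]) +
      dbetabinom_log(RD_vec[ok], DP_vec[ok], xi, od)
  }
  mx <- apply(lp, 1, max)
  pr <- exp(lp - mx)
  out[ok, ] <- pr / rowSums(pr)
  out
}

#' Estimate allelic bias and overdispersion by grid marginal likelihood
#'
#' Maximises the marginal log-likelihood
#' sum_i log sum_d prior(d) BetaBinomial(RD_i | DP_i, xi(d/K), od)
#' over a fixed grid: 15 log-spaced bias values in \[0.25, 2\] and 12
#' overdispersion values in \[0, 0.2\]. Degenerate data (all reads reference,
#' or none) return (1, 0) with a warning.
#'
#' @inheritParams noise_aware_posterior
#' @param seq_error fixed sequencing error used during the search.
#' @return List with elements `bias`, `od`, `loglik` (the maximised marginal
#'   log-likelihood).
#' @export
estimate_noise_params <- function(DP_vec, RD_vec, prior, seq_error = 0.001) {
  ok <- which(!is.na(DP_vec) & !is.na(RD_vec))
  if (length(ok) < 20)
    warning("fewer than 20 unmasked individuals; noise estimates unstable")
  dp <- DP_vec[ok]; rd <- RD_vec[ok]
  if (all(rd == 0) || all(rd == dp)) {
    warning("degenerate read counts (all reference or all alternative); ",
            "returning bias = 1, od = 0")
    return(list(bias = 1, od = 0, loglik = NA_real_))
  }
  bias_grid <- exp(seq(log(0.25), log(2), length.out = 15))
  od_grid <- c(0, 0.001, 0.002, 0.005, 0.01, 0.02, 0.03, 0.05,
               0.075, 0.1, 0.15, 0.2)
  K <- length(prior) - 1L
  ## collapse to unique (DP, RD) pairs: depth distributions are typically
  ## few-valued, which makes the grid search cheap
  key <- paste(dp, rd)
  u <- !duplicated(key)
  udp <- dp[u]; urd <- rd[u]
  cnt <- as.vector(table(factor(key, levels = key[u])))
  best <- list(bias = 1, od = 0, loglik = -Inf)
  for (b in bias_grid) {
    xi <- ref_fraction_xi((0:K) / K, b, seq_error)
    for (o in od_grid) {
      lp <- matrix(-Inf, length(udp), K + 1)
      for (d in 0:K) {
        if (prior[d + 1] <= 0) next
        lp[, d + 1] <- log(prior[d + 1]) +
          dbetabinom_log(urd, udp, xi[d + 1], o)
      }
      mx <- apply(lp, 1, max)
      ll <- sum(cnt * (mx + log(rowSums(exp(lp - mx)))))
      if (ll > best$loglik) best <- list(bias = b, od = o, loglik = ll)
    }
  }
  best
}
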