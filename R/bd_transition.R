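#' Linear birth-death transition probability for family size
#'
#' Probability that a gene family of size `s` evolves to size `c` over a
#' branch of duration `t` (million years) when each gene copy independently
#' duplicates at rate `lam` and is lost at rate `mu` (per gene per My).
#' Size 0 is absorbing: once a family is extinct it cannot be re-gained.
#'
#' The classical closed form is used. Each of the `s` ancestral copies
#' leaves 0 descendants with probability `alpha` and `k >= 1` descendants
#' with probability `(1-alpha)(1-beta) beta^(k-1)`, where for `lam != mu`
#' `alpha = mu(E-1)/(lam E - mu)`, `beta = lam(E-1)/(lam E - mu)` with
#' `E = exp((lam-mu) t)`, and in the critical case `lam = mu`,
#' `alpha = beta = lam t / (1 + lam t)`. Summing over the number of
#' surviving ancestral copies gives
#' \deqn{P(c|s) = \sum_j \binom{s}{j} \alpha^{s-j} \binom{c-1}{j-1}
#'   [(1-\alpha)(1-\beta)]^j \beta^{c-j}.}
#' The sum is evaluated in log space.
#'
#' @param s Parent (ancestral) family size, integer >= 0.
#' @param c Child family size; may be a vector.
#' @param lam Per-copy gain (duplication) rate, /gene/My.
#' @param mu Per-copy loss rate, /gene/My.
#' @param t Branch duration in My, > 0.
#' @return Numeric vector of probabilities, same length as `c`.
#' @examples
#' transition_probability(1, 0, 0.001, 0.001, 100)  # 0.1/1.1
#' @export
transition_probability <- function(s, c, lam, mu, t) {
  stopifnot(length(s) == 1L, s >= 0, all(c >= 0), lam >= 0, mu >= 0, t > 0)
  ab <- bd_alpha_beta(lam, mu, t)
  exp(log_trans_row(s, max(c), ab$alpha, ab$beta))[c + 1L]
}

# Extinction and geometric parameters of the per-copy offspring law.
bd_alpha_beta <- function(lam, mu, t) {
  if (lam == 0 && mu == 0) return(list(alpha = 0, beta = 0))
  if (abs(lam - mu) * t < 1e-8) {
    a <- lam * t / (1 + lam * t)
    return(list(alpha = a, beta = a))
  }
  E <- exp((lam - mu) * t)
  denom <- lam * E - mu
  list(alpha = mu * (E - 1) / denom, beta = lam * (E - 1) / denom)
}

# log P(c | s) for c = 0..cmax at fixed s, via logsumexp over the number of
# surviving ancestral lineages j.
log_trans_row <- function(s, cmax, alpha, beta) {
  cs <- 0:cmax
  out <- rep(-Inf, cmax + 1L)
  if (s == 0L) { out[1L] <- 0; return(out) }
  la <- if (alpha > 0) log(alpha) else -Inf
  lb <- if (beta > 0) log(beta) else -Inf
  l1a <- log1p(-alpha)
  l1b <- log1p(-beta)
  # c = 0: all s copies extinct
  out[1L] <- if (alpha > 0) s * la else if (s == 0L) 0 else -Inf
  if (cmax == 0L) return(out)
  jmax <- min(s, cmax)
  terms <- matrix(-Inf, nrow = jmax, ncol = cmax)
  for (j in seq_len(jmax)) {
    cc <- j:cmax
    lt <- lchoose(s, j) + j * (l1a + l1b) + lchoose(cc - 1L, j - 1L)
    lt <- lt + if (s - j > 0L) (s - j) * la else 0
    extra <- cc - j
    lt <- lt + ifelse(extra > 0L, extra * lb, 0)
    terms[j, cc] <- lt
  }
  mx <- apply(terms, 2L, max)
  fin <- is.finite(mx)
  res <- rep(-Inf, cmax)
  if (any(fin))
    res[fin] <- mx[fin] +
      log(colSums(exp(sweep(terms[, fin, drop = FALSE], 2L, mx[fin]))))
  out[-1L] <- res
  out
}

#' Transition matrix over truncated size states
#'
#' @inheritParams transition_probability
#' @param S State-space cap; states are `0..S`.
#' @return `(S+1) x (S+1)` matrix `T[s+1, c+1] = P(c|s)`. Rows sum to
#'   slightly below 1 when mass escapes past the truncation.
#' @export
transition_matrix <- function(lam, mu, t, S) {
  ab <- bd_alpha_beta(lam, mu, t)
  alpha <- ab$alpha; beta <- ab$beta
  ix <- trans_index(S)
  la <- if (alpha > 0) log(alpha) else -Inf
  lb <- if (beta > 0) log(beta) else -Inf
  l1 <- log1p(-alpha) + log1p(-beta)
  # per-survivor-count log terms; each term is one configuration's
  # probability (<= 1), so direct exp+sum cannot overflow
  lt <- ix$lch + ix$j * l1
  sj <- ix$s - ix$j
  lt <- lt + ifelse(sj > 0L, sj * la, 0)
  cj <- ix$c - ix$j
  lt <- lt + ifelse(cj > 0L, cj * lb, 0)
  out <- matrix(0, S + 1L, S + 1L)
  acc <- rowsum(exp(lt), ix$grp)
  out[as.integer(rownames(acc))] <- acc
  # c = 0 column: all s copies extinct; s = 0 row: absorbing
  out[, 1L] <- if (alpha > 0) alpha ^ (0:S) else c(1, rep(0, S))
  out[1L, ] <- c(1, rep(0, S))
  out
}

# Cached (s, c, j) survivor-sum index for state cap S, with the constant
# log-binomial part precomputed.
trans_index <- local({
  cache <- list()
  function(S) {
    key <- as.character(S)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- rep(1:S, each = S)
    c <- rep(1:S, times = S)
    j <- sequence(pmin(s, c))
    n <- pmin(s, c)
    s <- rep(s, n); c <- rep(c, n)
    ix <- list(s = s, c = c, j = j,
               lch = lchoose(s, j) + lchoose(c - 1L, j - 1L),
               grp = s + 1L + (S + 1L) * c)  # linear index into (s+1, c+1)
    cache[[key]] <<- ix
    ix
  }
})

#' Annotation-error observation probability
#'
#' Models assembly/annotation miscounts as a +/-1 channel: the observed
#' count equals the true count with probability `1 - eps` and deviates by
#' one in either direction with probability `eps/2` each. At a true count
#' of 0 the inadmissible -1 outcome is folded back, so
#' `P(0|0) = 1 - eps/2` and `P(1|0) = eps/2`; rows sum to one.
#'
#' @param true_count True family size(s), integer >= 0.
#' @param obs_count Observed count(s), integer >= 0.
#' @param eps Error probability in `[0, 1)`; `eps = 0` is the identity
#'   channel.
#' @return Probability vector (recycled over the longer argument).
#' @examples
#' observation_probability(5, 4, 0.2)  # 0.1
#' @export
observation_probability <- function(true_count, obs_count, eps) {
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)", call. = FALSE)
  stopifnot(all(true_count >= 0), all(obs_count >= 0))
  n <- max(length(true_count), length(obs_count))
  tc <- rep_len(true_count, n); oc <- rep_len(obs_count, n)
  p <- numeric(n)
  p[oc == tc] <- 1 - eps
  p[abs(oc - tc) == 1] <- eps / 2
  p[tc == 0 & oc == 0] <- 1 - eps / 2
  p
}

# Observation matrix O[true+1, obs+1] over states 0..S (obs 0..S).
observation_matrix <- function(eps, S) {
  O <- diag(1 - eps, S + 1L)
  if (S >= 1L) {
    idx <- seq_len(S)
    O[cbind(idx, idx + 1L)] <- eps / 2
    O[cbind(idx + 1L, idx)] <- eps / 2
  }
  O[1L, 1L] <- 1 - eps / 2
  O
}
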