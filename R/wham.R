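.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Weighted histogram analysis of multi-temperature samples
#'
#' Combines potential-energy samples collected at several ladder
#' temperatures into a consistent density of states, by iterating the
#' standard two WHAM equations until the per-temperature free energies
#' change by less than `tol`.  Temperatures are in reduced units
#' (k_B T / epsilon), energies in epsilon.
#'
#' @param energy numeric vector of sampled potential energies.
#' @param temp_index integer vector: ladder index of each sample.
#' @param temperatures the ladder (k_B T / epsilon).
#' @param n_bins number of energy bins.
#' @param tol convergence tolerance on the free-energy increments.
#' @param max_iter iteration cap.
#' @return A `wham_fit`: list with `f` (dimensionless free energies,
#'   `f[k] = -ln Z_k`, first entry pinned to 0), `bins`, `log_omega`
#'   (log density of states per occupied bin), the sample data, and the
#'   iteration diagnostics.
#' @export
wham <- function(energy, temp_index, temperatures, n_bins = 200,
                 tol = 1e-7, max_iter = 1e5) {
  stopifnot(length(energy) == length(temp_index))
  K <- length(temperatures)
  beta <- 1 / temperatures
  N_k <- tabulate(temp_index, K)
  if (any(N_k == 0)) stop("no samples at ladder temperature ",
                          which(N_k == 0)[1])

  edges <- seq(min(energy), max(energy), length.out = n_bins + 1)
  edges[n_bins + 1] <- edges[n_bins + 1] + 1e-9
  bin <- findInterval(energy, edges, rightmost.closed = TRUE)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2

  n_kb <- matrix(0, K, n_bins)
  for (k in seq_len(K)) {
    n_kb[k, ] <- tabulate(bin[temp_index == k], n_bins)
  }
  # histogram-overlap diagnostic between adjacent temperatures
  if (K > 1) {
    for (k in seq_len(K - 1)) {
      ov <- sum(n_kb[k, ] > 0 & n_kb[k + 1, ] > 0)
      if (ov == 0) {
        stop("energy histograms of ladder temperatures ", k, " and ", k + 1,
             " do not overlap; add intermediate temperatures")
      }
    }
  }

  occ <- which(colSums(n_kb) > 0)
  log_n_b <- log(colSums(n_kb)[occ])
  E_b <- centers[occ]
  logN <- log(N_k)

  f <- numeric(K)
  for (it in seq_len(max_iter)) {
    # log Omega_b = log(sum_k n_kb) - logsumexp_k(log N_k + f_k - beta_k E_b)
    A <- outer(logN + f, E_b, function(a, e) a) -
      outer(beta, E_b)                       # K x B
    denom <- apply(A, 2, .logsumexp)
    log_omega <- log_n_b - denom
    f_new <- -vapply(seq_len(K),
                     function(k) .logsumexp(log_omega - beta[k] * E_b),
                     numeric(1))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    warning("WHAM did not converge to ", tol, " in ", max_iter,
            " iterations (last increment ", signif(delta, 3), ")")
  }

  structure(list(
    f = f, temperatures = temperatures, beta = beta,
    bins = E_b, log_omega = log_omega,
    energy = energy, temp_index = temp_index, N_k = N_k,
    iterations = it, increment = delta
  ), class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat("<wham_fit> ", length(x$energy), " samples at ",
      length(x$temperatures), " temperatures; converged in ",
      x$iterations, " iterations (increment ", signif(x$increment, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Per-sample reweighting weights at a target temperature
#'
#' \eqn{w_i \propto e^{-\beta E_i} / \sum_k N_k e^{f_k - \beta_k E_i}},
#' normalised to sum to 1.
#'
#' @param fit a [wham()] fit.
#' @param target_T target temperature (k_B T / epsilon).
#' @return numeric weights, one per sample.
#' @export
wham_weights <- function(fit, target_T) {
  beta_t <- 1 / target_T
  E <- fit$energy
  denom <- vapply(E, function(e) {
    .logsumexp(log(fit$N_k) + fit$f - fit$beta * e)
  }, numeric(1))
  lw <- -beta_t * E - denom
  w <- exp(lw - .logsumexp(lw))
  w
}

#' Reweighted ensemble average of an observable
#'
#' @param fit a [wham()] fit.
#' @param observable numeric vector aligned with the samples.
#' @param target_T target temperature(s).
#' @param se_method `"block"` (default): standard error from block averages
#'   over contiguous sample blocks, which absorbs the autocorrelation of the
#'   dynamics; `"weighted"`: naive effective-sample-size error, valid only
#'   for uncorrelated samples.
#' @param n_blocks number of blocks for the block estimate.
#' @return data.frame with `temperature`, `mean`, `se` and the effective
#'   sample size.
#' @export
reweight_observable <- function(fit, observable, target_T,
                                se_method = c("block", "weighted"),
                                n_blocks = 20) {
  stopifnot(length(observable) == length(fit$energy))
  se_method <- match.arg(se_method)
  out <- lapply(target_T, function(tt) {
    w <- wham_weights(fit, tt)
    m <- sum(w * observable)
    ess <- 1 / sum(w^2)
    if (se_method == "weighted") {
      se <- sqrt(sum(w * (observable - m)^2) / ess)
    } else {
      n <- length(observable)
      bid <- ceiling(seq_len(n) / (n / n_blocks))
      bm <- vapply(seq_len(n_blocks), function(b) {
        sel <- bid == b
        sum(w[sel] * observable[sel]) / sum(w[sel])
      }, numeric(1))
      bm <- bm[is.finite(bm)]
      se <- stats::sd(bm) / sqrt(length(bm))
    }
    data.frame(temperature = tt, mean = m, se = se, ess = ess)
  })
  do.call(rbind, out)
}
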