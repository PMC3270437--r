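#' Blockwise random-walk Metropolis sampler
#'
#' Gaussian random-walk Metropolis with blockwise updates and
#' Robbins-Monro adaptation of the per-block proposal scales toward a
#' target acceptance rate during burn-in only (scales are frozen
#' afterwards, preserving detailed balance for the retained draws).
#' Parameters are expected on an unconstrained (typically log) scale; any
#' Jacobian terms belong in the target.
#'
#' The target may be a plain function \code{function(theta)} returning
#' the log posterior, or - for expensive likelihoods with cached
#' components - a list of functions \code{init(theta)},
#' \code{propose(theta, block)}, \code{accept()}, \code{reject()}, where
#' \code{propose} may reuse cached per-block quantities and
#' \code{accept}/\code{reject} commit or discard the proposed cache.
#'
#' @param target Log-posterior function or cached-target list (above).
#' @param init Named numeric vector of starting values.
#' @param n_iter Number of iterations (full sweeps over all blocks).
#' @param blocks List of index (or name) vectors partitioning the
#'   parameters; default one block containing everything.
#' @param scales Initial proposal SD per block (recycled).
#' @param target_acceptance Acceptance rate the adaptation aims for.
#' @param burn_in Number of initial iterations treated as burn-in
#'   (adaptation window; discarded by summaries).
#' @param adapt Adapt proposal scales during burn-in?
#' @param seed Integer seed making the chain exactly reproducible.
#' @param thin Keep every \code{thin}-th iteration.
#' @return Object of class \code{mcmc_chain}: \code{samples} (matrix,
#'   all kept iterations including burn-in), \code{log_post},
#'   \code{acceptance} (per block, post burn-in), \code{scales} (final),
#'   plus the settings needed for exact replay.
#' @examples
#' ch <- metropolis_run(function(x) -0.5 * sum(x^2), c(x = 0),
#'                      n_iter = 2000, seed = 1)
#' @export
metropolis_run <- function(target, init, n_iter, blocks = NULL,
                           scales = NULL, target_acceptance = 0.1,
                           burn_in = floor(0.4 * n_iter), adapt = TRUE,
                           seed = NULL, thin = 1L) {
  stopifnot(n_iter >= 1, is.numeric(init), length(init) >= 1)
  if (is.function(target)) {
    f <- target
    target <- list(init = f, propose = function(theta, block) f(theta),
                   accept = function() NULL, reject = function() NULL)
  }
  if (is.null(blocks)) blocks <- list(seq_along(init))
  blocks <- lapply(blocks, function(b) {
    if (is.character(b)) b <- match(b, names(init))
    if (anyNA(b) || any(b < 1) || any(b > length(init)))
      stop("metropolis_run: invalid block index", call. = FALSE)
    as.integer(b)
  })
  nb <- length(blocks)
  if (is.null(scales)) scales <- rep(0.1, nb)
  scales <- rep_len(scales, nb)
  if (any(scales <= 0))
    stop("metropolis_run: proposal scales must be positive",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  theta <- init
  lp <- target$init(theta)
  if (!is.finite(lp))
    stop("metropolis_run: initial state has non-finite log posterior",
         call. = FALSE)
  n_keep <- floor(n_iter / thin)
  samples <- matrix(NA_real_, n_keep, length(init),
                    dimnames = list(NULL, names(init)))
  log_post <- numeric(n_keep)
  acc_post <- integer(nb)   # acceptances after burn-in
  n_post <- 0L
  dry_spell <- 0L
  warned <- FALSE

  for (it in seq_len(n_iter)) {
    any_acc <- FALSE
    for (b in seq_len(nb)) {
      idx <- blocks[[b]]
      prop <- theta
      prop[idx] <- prop[idx] + rnorm(length(idx), 0, scales[b])
      lp_prop <- target$propose(prop, b)
      accept <- is.finite(lp_prop) && log(runif(1)) < lp_prop - lp
      if (accept) {
        target$accept()
        theta <- prop
        lp <- lp_prop
        any_acc <- TRUE
      } else {
        target$reject()
      }
      if (it > burn_in) acc_post[b] <- acc_post[b] + accept
      if (adapt && it <= burn_in)
        scales[b] <- scales[b] *
          exp((as.numeric(accept) - target_acceptance) / it^0.55)
    }
    if (it > burn_in) n_post <- n_post + 1L
    dry_spell <- if (any_acc) 0L else dry_spell + 1L
    if (dry_spell >= 1000L && !warned) {
      warning("metropolis_run: no proposal accepted for 1000 ",
              "consecutive iterations", call. = FALSE)
      warned <- TRUE
    }
    if (it %% thin == 0L) {
      k <- it %/% thin
      samples[k, ] <- theta
      log_post[k] <- lp
    }
  }
  structure(list(samples = samples, log_post = log_post,
                 acceptance = if (n_post > 0) acc_post / n_post else
                   rep(NA_real_, nb),
                 scales = scales, burn_in = burn_in, thin = thin,
                 n_iter = n_iter, seed = seed, blocks = blocks,
                 target_acceptance = target_acceptance),
            class = "mcmc_chain")
}

#' Post-burn-in samples of a chain
#'
#' @param chain An \code{mcmc_chain}.
#' @param discard_burn_in Drop the burn-in portion?
#' @return Matrix of samples.
#' @export
chain_samples <- function(chain, discard_burn_in = TRUE) {
  stopifnot(inherits(chain, "mcmc_chain"))
  s <- chain$samples
  if (discard_burn_in) {
    drop_k <- floor(chain$burn_in / chain$thin)
    if (drop_k > 0) s <- s[-seq_len(drop_k), , drop = FALSE]
  }
  s
}

#' Columnar view of a chain
#'
#' @param x An \code{mcmc_chain}.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with \code{iteration}, one column per parameter,
#'   and \code{log_post}; suitable for writing to delimited text.
#' @export
as.data.frame.mcmc_chain <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  out <- data.frame(iteration = seq_len(nrow(x$samples)) * x$thin,
                    x$samples, log_post = x$log_post,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("Metropolis chain: ", x$n_iter, " iterations, ",
      ncol(x$samples), " parameters, ", length(x$blocks),
      " blocks\n", sep = "")
  cat("  post-burn-in acceptance per block: ",
      paste(sprintf("%.2f", x$acceptance), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic \eqn{\hat R} from between- and within-chain variances: with
#' \eqn{m} chains of length \eqn{n}, \eqn{W} the mean within-chain
#' variance and \eqn{B/n} the variance of the chain means,
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \; W + B/n}{W}}.}
#' Chains that are exact copies give \eqn{\hat R = \sqrt{(n-1)/n} \le 1};
#' a parameter with zero within-chain variance but scattered chain means
#' is degenerate and reported as \code{Inf}.
#'
#' @param chains List of at least two \code{mcmc_chain} objects, or of
#'   equal-length numeric matrices/vectors (aligned columns).
#' @param discard_burn_in For \code{mcmc_chain} inputs, drop burn-in
#'   first.
#' @return Named vector of \eqn{\hat R}, one per parameter.
#' @export
gelman_rubin <- function(chains, discard_burn_in = TRUE) {
  stopifnot(is.list(chains), length(chains) >= 2)
  mats <- lapply(chains, function(ch) {
    if (inherits(ch, "mcmc_chain")) ch <- chain_samples(ch,
                                                        discard_burn_in)
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = 1)
    ch
  })
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1)
    stop("gelman_rubin: chains must have equal lengths", call. = FALSE)
  if (n < 10)
    stop("gelman_rubin: need at least 10 draws per chain",
         call. = FALSE)
  p <- ncol(mats[[1]])
  out <- vapply(seq_len(p), function(j) {
    xs <- vapply(mats, function(m) m[, j], numeric(n))
    W <- mean(apply(xs, 2, var))
    Bn <- var(colMeans(xs))            # B/n
    if (W == 0) return(Inf)   # degenerate: no within-chain variation
    sqrt(((n - 1) / n * W + Bn) / W)
  }, numeric(1))
  names(out) <- colnames(mats[[1]])
  out
}
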