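# NMIG spike-and-slab Bayesian logistic mixed model.
#
# Model: y_i ~ Bern(p_i), logit(p_i) = x_i' beta + gamma_i (+ omega_i in the
# two-stage measurement-error variant).  Selectable coefficients carry the
# Normal-mixture-of-inverse-Gammas prior
#     beta_j | eta_b, tau2_b ~ N(0, tau2_b * eta_b),   eta_b in {v0, 1},
#     tau2_b ~ InvGamma(a_tau, b_tau),  P(eta_b = 1) = w,  w ~ Beta(a_w, b_w),
# which places a spike (eta = v0, v0 small) or slab (eta = 1) on the
# coefficient variance; the posterior frequency of eta = 1 is the term's
# inclusion probability.  Non-selectable coefficients get zero-mean Gaussian
# priors with Ga(1, 5e-05) precision, as does the random-intercept precision
# when the intercept block is not itself under selection.  The Bernoulli
# likelihood is handled by exact Polya-Gamma auxiliary-variable augmentation,
# giving a full Gibbs sampler with conjugate conditional updates throughout.

#' NMIG hyperparameters
#'
#' @param v0 spike constant, small positive (< 1).
#' @param a_tau,b_tau inverse-Gamma shape/scale for the coefficient
#'   variance tau^2.
#' @param a_w,b_w Beta parameters of the slab probability w.
#' @param fixed_shape,fixed_rate Gamma prior on the precision of each
#'   non-selectable coefficient (default Ga(1, 5e-05)).
#' @param ri_shape,ri_rate Gamma prior on the random-intercept precision
#'   when the intercept block is not selectable (default Ga(1, 5e-05)).
#' @param fixed_precision optional fixed precision for non-selectable
#'   coefficients; overrides the Gamma prior when supplied (useful for
#'   near-flat reference fits).
#' @return object of class `nmig_hyperparams`.
#' @export
nmig_hyperparams <- function(v0 = 0.00025, a_tau = 5, b_tau = 25,
                             a_w = 1, b_w = 1,
                             fixed_shape = 1, fixed_rate = 5e-05,
                             ri_shape = 1, ri_rate = 5e-05,
                             fixed_precision = NULL) {
  stopifnot(v0 > 0, v0 < 1, a_tau > 0, b_tau > 0, a_w > 0, b_w > 0,
            fixed_shape > 0, fixed_rate > 0, ri_shape > 0, ri_rate > 0)
  structure(list(v0 = v0, a_tau = a_tau, b_tau = b_tau, a_w = a_w,
                 b_w = b_w, fixed_shape = fixed_shape,
                 fixed_rate = fixed_rate, ri_shape = ri_shape,
                 ri_rate = ri_rate, fixed_precision = fixed_precision),
            class = "nmig_hyperparams")
}

#' Linear model term
#'
#' @param name term label.
#' @param x numeric covariate vector (standardized internally).
#' @param selectable whether the term is under spike-and-slab selection.
#' @return object of class `model_term`.
#' @export
term_linear <- function(name, x, selectable = TRUE) {
  structure(list(name = name, kind = "linear", x = as.numeric(x),
                 selectable = isTRUE(selectable)), class = "model_term")
}

#' Smooth model term (first-order random-walk penalty)
#'
#' Flexible effect of a continuous covariate via a first-order random-walk
#' smoother: the covariate is binned at `n_basis` quantile knots, the RW1
#' difference penalty is eigen-decomposed, and the penalized subspace is
#' rescaled so the block coefficients are exchangeable N(0, tau^2 eta) —
#' letting the whole smooth be selected in or out with a single indicator.
#' The null space (constant) is absorbed by the model intercept.
#'
#' @param name term label.
#' @param x numeric covariate vector.
#' @param n_basis number of random-walk bins (default 8).
#' @param selectable whether the block is under selection.
#' @return object of class `model_term`.
#' @export
term_smooth <- function(name, x, n_basis = 8, selectable = TRUE) {
  stopifnot(n_basis >= 3)
  structure(list(name = name, kind = "smooth", x = as.numeric(x),
                 n_basis = as.integer(n_basis),
                 selectable = isTRUE(selectable)), class = "model_term")
}

# RW1 design block: bin incidence matrix projected onto the penalized
# eigenspace of K = D'D, scaled to unit prior variance per coefficient
rw1_basis <- function(x, n_basis) {
  knots <- unique(quantile(x, probs = seq(0, 1, length.out = n_basis + 1)))
  bins <- cut(x, knots, include.lowest = TRUE)
  B <- model.matrix(~ bins - 1)
  q <- ncol(B)
  if (q < 2) stop("covariate too coarse for a smooth term", call. = FALSE)
  D <- diff(diag(q))
  K <- crossprod(D)
  eig <- eigen(K, symmetric = TRUE)
  pos <- eig$values > 1e-8
  Z <- B %*% eig$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eig$values[pos]), sum(pos))
  sweep(Z, 2, colMeans(Z))        # centre: constant lives in the intercept
}

inv_gamma_draw <- function(n, shape, scale) 1 / rgamma(n, shape, rate = scale)

#' Conditional slab probability of the NMIG indicator
#'
#' The exact full conditional P(eta = 1 | beta, tau^2, w) used inside the
#' Gibbs sampler: the posterior odds of slab versus spike given the current
#' coefficient value(s) of the block,
#' \deqn{\frac{w\,N(\beta; 0, \tau^2)}{w\,N(\beta; 0, \tau^2) +
#'   (1-w)\,N(\beta; 0, v_0 \tau^2)}.}
#' For a block (vector `beta`) the densities multiply across elements.
#'
#' @param beta coefficient value, or vector for a block.
#' @param tau2 variance parameter, > 0.
#' @param w slab prior probability in \[0, 1\].
#' @param v0 spike constant in (0, 1).
#' @return probability that the indicator sits in the slab.
#' @export
conditional_eta_probability <- function(beta, tau2, w, v0) {
  if (any(tau2 <= 0)) stop("tau2 must be positive", call. = FALSE)
  stopifnot(w >= 0, w <= 1, v0 > 0, v0 < 1)
  if (w == 0) return(0)
  if (w == 1) return(1)
  l1 <- log(w) + sum(dnorm(beta, 0, sqrt(tau2), log = TRUE))
  l0 <- log1p(-w) + sum(dnorm(beta, 0, sqrt(v0 * tau2), log = TRUE))
  1 / (1 + exp(l0 - l1))
}

#' Conditional draw of the NMIG variance tau^2
#'
#' Full conditional of a block variance given its coefficients and
#' indicator: InvGamma(a_tau + q/2, b_tau + sum(beta^2)/(2 eta)).
#' Exposed so the conditional can be checked distributionally.
#'
#' @param n number of draws.
#' @param beta block coefficient vector.
#' @param eta current indicator value (v0 or 1).
#' @param a_tau,b_tau inverse-Gamma prior shape/scale.
#' @return numeric vector of draws.
#' @export
draw_tau2_conditional <- function(n, beta, eta, a_tau = 5, b_tau = 25) {
  stopifnot(eta > 0, a_tau > 0, b_tau > 0)
  inv_gamma_draw(n, a_tau + length(beta) / 2,
                 b_tau + sum(beta^2) / (2 * eta))
}

# split-Rhat over a single merged chain vector (split in half) or per chain
split_rhat <- function(x, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2)
    if (h < 2) return(NA_real_)
    pieces <- c(pieces, list(v[seq_len(h)]), list(v[h + seq_len(h)]))
  }
  m <- length(pieces); nn <- length(pieces[[1]])
  means <- vapply(pieces, mean, 0); vars <- vapply(pieces, var, 0)
  B <- nn * var(means); W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit the NMIG spike-and-slab Bayesian logistic mixed model
#'
#' Gibbs sampler for a logistic mixed model with spike-and-slab variable
#' selection.  All candidate columns are standardized to zero mean / unit
#' variance before selection (the NMIG prior is scale-sensitive);
#' coefficients are reported on the standardized scale.  The likelihood is
#' augmented with exact Polya-Gamma draws, so every conditional update is
#' conjugate.  Smooth terms are selected as a block with one indicator.
#'
#' @param y binary outcome vector (0/1).
#' @param terms list of [term_linear()] / [term_smooth()] objects.
#' @param hyper a [nmig_hyperparams()] object.
#' @param n_iter,burnin,thin MCMC iterations, burn-in, thinning (defaults
#'   10000 / 5000 / 5).
#' @param chains number of chains, run sequentially from consecutive seeds
#'   (default 3); split-Rhat on coefficients is reported.
#' @param seed integer seed for the first chain.
#' @param random_intercept include a per-participant random intercept.
#' @param ri_selectable treat the random-intercept block itself as a
#'   selectable NMIG block (its inclusion probability is then reported, as
#'   `Rnd(id2)`); if FALSE the intercept variance gets the Ga(1, 5e-05)
#'   precision prior and is always in the model.
#' @param me_variance optional per-observation known variances of an
#'   additive measurement-error term in the linear predictor (used by the
#'   two-stage validation model); zeros disable the term for that
#'   observation.
#' @param prior_only if TRUE the likelihood is switched off and the
#'   sampler explores the prior (for prior-predictive checks).
#' @return object of class `ssvs_fit` with element `draws` (matrices
#'   beta, eta, tau2, gamma, omega; vectors w, chain) plus term metadata,
#'   split-Rhat values, and the MCMC settings.
#' @export
fit_ssvs_logistic <- function(y, terms, hyper = nmig_hyperparams(),
                              n_iter = 10000, burnin = 5000, thin = 5,
                              chains = 3, seed = 1,
                              random_intercept = TRUE,
                              ri_selectable = TRUE,
                              me_variance = NULL,
                              prior_only = FALSE) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(terms) == 0L && !random_intercept)
    stop("empty term list", call. = FALSE)
  if (n_iter <= 0 || burnin < 0 || thin < 1 || burnin >= n_iter)
    stop("invalid MCMC settings", call. = FALSE)
  n <- length(y)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)

  # ---- assemble standardized design ------------------------------------
  cols <- list(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  col_term <- c(NA_integer_)          # term index per column (NA: intercept)
  blocks <- list(); block_names <- character(0)
  selectable_cols <- c(FALSE)
  for (ti in seq_along(terms)) {
    tm <- terms[[ti]]
    if (!inherits(tm, "model_term")) stop("terms must be model_term objects",
                                          call. = FALSE)
    if (length(tm$x) != n) stop("term '", tm$name, "' length mismatch",
                                call. = FALSE)
    if (tm$kind == "linear") {
      s <- sd(tm$x)
      if (s == 0) stop("term '", tm$name, "' is constant", call. = FALSE)
      M <- matrix((tm$x - mean(tm$x)) / s, ncol = 1,
                  dimnames = list(NULL, tm$name))
    } else {
      Z <- rw1_basis(tm$x, tm$n_basis)
      colnames(Z) <- paste0(tm$name, ".rw", seq_len(ncol(Z)))
      M <- Z
    }
    start <- sum(vapply(cols, ncol, 0L))
    cols <- c(cols, list(M))
    col_term <- c(col_term, rep(ti, ncol(M)))
    selectable_cols <- c(selectable_cols, rep(tm$selectable, ncol(M)))
    if (tm$selectable) {
      blocks <- c(blocks, list(start + seq_len(ncol(M))))
      block_names <- c(block_names, tm$name)
    }
  }
  X <- do.call(cbind, cols)
  p <- ncol(X)
  nb <- length(blocks)
  has_ri <- isTRUE(random_intercept)
  ri_sel <- has_ri && isTRUE(ri_selectable)
  use_me <- !is.null(me_variance) && any(me_variance > 0)
  if (use_me && length(me_variance) != n)
    stop("me_variance length mismatch", call. = FALSE)
  me_v <- if (use_me) pmax(me_variance, 0) else rep(0, n)
  fixed_idx <- which(!selectable_cols)
  kappa <- y - 0.5
  v0 <- hyper$v0

  n_rec <- floor((n_iter - burnin) / thin)
  total_rec <- n_rec * chains
  all_names <- c(colnames(X))
  eta_names <- c(block_names, if (ri_sel) "Rnd(id2)")
  rec <- list(beta = matrix(NA_real_, total_rec, p,
                            dimnames = list(NULL, all_names)),
              eta = matrix(NA_real_, total_rec, length(eta_names),
                           dimnames = list(NULL, eta_names)),
              tau2 = matrix(NA_real_, total_rec, length(eta_names),
                            dimnames = list(NULL, eta_names)),
              w = numeric(total_rec),
              gamma = if (has_ri) matrix(NA_real_, total_rec, n) else NULL,
              omega = if (use_me) matrix(NA_real_, total_rec, n) else NULL,
              chain = integer(total_rec))

  row0 <- 0L
  for (ch in seq_len(chains)) {
    set.seed((seed + ch - 1L) %% .Machine$integer.max)
    # ---- initial state -------------------------------------------------
    beta <- rep(0, p)
    eta <- rep(1, nb)
    tau2 <- rep(hyper$b_tau / (hyper$a_tau + 1), nb)
    w <- hyper$a_w / (hyper$a_w + hyper$b_w)
    tau_fixed <- rep(if (is.null(hyper$fixed_precision)) 1
                     else hyper$fixed_precision, length(fixed_idx))
    gam <- rep(0, n); tau_g <- 1
    eta_g <- 1; tau2_g <- hyper$b_tau / (hyper$a_tau + 1)
    ome <- rep(0, n)

    for (it in seq_len(n_iter)) {
      # prior precisions of the regression coefficients
      dprec <- numeric(p)
      if (length(fixed_idx)) dprec[fixed_idx] <- tau_fixed
      for (b in seq_len(nb)) dprec[blocks[[b]]] <- 1 / (tau2[b] * eta[b])

      if (!prior_only) {
        psi <- as.vector(X %*% beta) + gam + ome
        pg <- rpg_devroye(psi)
        # beta | rest
        Prec <- crossprod(X * pg, X)
        diag(Prec) <- diag(Prec) + dprec
        bvec <- as.vector(crossprod(X, kappa - pg * (gam + ome)))
        R <- chol(Prec)
        mu <- backsolve(R, forwardsolve(t(R), bvec))
        beta <- mu + backsolve(R, rnorm(p))
        xb <- as.vector(X %*% beta)
        # random intercepts
        if (has_ri) {
          prec_g <- pg + if (ri_sel) 1 / (tau2_g * eta_g) else tau_g
          mg <- (kappa - pg * (xb + ome)) / prec_g
          gam <- rnorm(n, mg, 1 / sqrt(prec_g))
        }
        # measurement-error offsets with known variances
        if (use_me) {
          pos <- me_v > 0
          prec_o <- pg[pos] + 1 / me_v[pos]
          mo <- (kappa[pos] - pg[pos] * (xb[pos] + gam[pos])) / prec_o
          ome[pos] <- rnorm(sum(pos), mo, 1 / sqrt(prec_o))
        }
      } else {
        beta <- rnorm(p, 0, 1 / sqrt(dprec))
        if (has_ri) {
          sd_g <- if (ri_sel) sqrt(tau2_g * eta_g) else 1 / sqrt(tau_g)
          gam <- rnorm(n, 0, sd_g)
        }
      }

      # NMIG indicators, variances, slab weight
      n_slab <- 0L; n_spike <- 0L
      for (b in seq_len(nb)) {
        pr <- conditional_eta_probability(beta[blocks[[b]]], tau2[b], w, v0)
        eta[b] <- if (runif(1) < pr) 1 else v0
        if (eta[b] == 1) n_slab <- n_slab + 1L else n_spike <- n_spike + 1L
        tau2[b] <- draw_tau2_conditional(1, beta[blocks[[b]]], eta[b],
                                         hyper$a_tau, hyper$b_tau)
      }
      if (ri_sel) {
        pr <- conditional_eta_probability(gam, tau2_g, w, v0)
        eta_g <- if (runif(1) < pr) 1 else v0
        if (eta_g == 1) n_slab <- n_slab + 1L else n_spike <- n_spike + 1L
        tau2_g <- draw_tau2_conditional(1, gam, eta_g,
                                        hyper$a_tau, hyper$b_tau)
      }
      if (nb + ri_sel > 0)
        w <- rbeta(1, hyper$a_w + n_slab, hyper$b_w + n_spike)
      # precisions of non-selectable coefficients and plain random intercept
      if (length(fixed_idx) && is.null(hyper$fixed_precision))
        tau_fixed <- rgamma(length(fixed_idx), hyper$fixed_shape + 0.5,
                            rate = hyper$fixed_rate + beta[fixed_idx]^2 / 2)
      if (has_ri && !ri_sel)
        tau_g <- rgamma(1, hyper$ri_shape + n / 2,
                        rate = hyper$ri_rate + sum(gam^2) / 2)

      if (it > burnin && (it - burnin) %% thin == 0) {
        r <- row0 + (it - burnin) %/% thin
        rec$beta[r, ] <- beta
        if (length(eta_names))
          rec$eta[r, ] <- c(eta, if (ri_sel) eta_g)
        if (length(eta_names))
          rec$tau2[r, ] <- c(tau2, if (ri_sel) tau2_g)
        rec$w[r] <- w
        if (has_ri) rec$gamma[r, ] <- gam
        if (use_me) rec$omega[r, ] <- ome
        rec$chain[r] <- ch
      }
    }
    row0 <- row0 + n_rec
  }

  rhat <- apply(rec$beta, 2, split_rhat, chain = rec$chain)
  structure(list(draws = rec,
                 terms = terms,
                 blocks = blocks,
                 block_names = block_names,
                 eta_names = eta_names,
                 col_names = all_names,
                 col_term = col_term,
                 v0 = v0,
                 hyper = hyper,
                 random_intercept = has_ri,
                 ri_selectable = ri_sel,
                 rhat = rhat,
                 mcmc = list(n_iter = n_iter, burnin = burnin, thin = thin,
                             chains = chains, seed = seed,
                             n_recorded = total_rec)),
            class = "ssvs_fit")
}

#' @export
print.ssvs_fit <- function(x, ...) {
  cat("NMIG spike-and-slab logistic fit:",
      x$mcmc$n_recorded, "recorded draws (",
      x$mcmc$chains, "chain(s) x", x$mcmc$n_iter, "iterations, burn-in",
      x$mcmc$burnin, ", thin", x$mcmc$thin, ")\n")
  cat("  max split-Rhat(beta):", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  print(inclusion_summary(x))
  invisible(x)
}

#' Posterior inclusion summary
#'
#' Per selectable term: posterior mean and standard deviation of the slab
#' indicator event, classification against the inclusion (c = 0.5, ties
#' included) and reporting (c = 0.25) thresholds, and — for included
#' linear terms — the posterior mean coefficient with an equal-tailed 95%
#' credible interval.  A term whose interval excludes zero is starred as
#' well estimated.
#'
#' @param samples an `ssvs_fit`.
#' @param c_include inclusion threshold on the mean inclusion probability
#'   (default 0.5).
#' @param c_report reporting threshold (default 0.25).
#' @return data frame of class `inclusion_summary` with columns term,
#'   incl_mean, incl_sd, classification, estimate, ci_lower, ci_upper,
#'   well_estimated.
#' @export
inclusion_summary <- function(samples, c_include = 0.5, c_report = 0.25) {
  stopifnot(inherits(samples, "ssvs_fit"))
  if (samples$mcmc$n_recorded < 1) stop("no recorded draws", call. = FALSE)
  en <- samples$eta_names
  out <- data.frame(term = en,
                    incl_mean = NA_real_, incl_sd = NA_real_,
                    classification = NA_character_,
                    estimate = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_, well_estimated = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(en)) {
    ind <- as.numeric(samples$draws$eta[, i] == 1)
    out$incl_mean[i] <- mean(ind)
    out$incl_sd[i] <- sd(ind)
    out$classification[i] <-
      if (out$incl_mean[i] >= c_include) "included"
      else if (out$incl_mean[i] >= c_report) "reported" else "excluded"
    # coefficient summary for included single-column (linear) blocks
    if (out$classification[i] == "included" && en[i] %in% samples$block_names) {
      b <- which(samples$block_names == en[i])
      idx <- samples$blocks[[b]]
      if (length(idx) == 1L) {
        dr <- samples$draws$beta[, idx]
        out$estimate[i] <- mean(dr)
        ci <- unname(quantile(dr, c(0.025, 0.975)))
        out$ci_lower[i] <- ci[1]; out$ci_upper[i] <- ci[2]
        out$well_estimated[i] <- ci[1] > 0 || ci[2] < 0
      }
    }
  }
  class(out) <- c("inclusion_summary", "data.frame")
  out
}

#' @export
print.inclusion_summary <- function(x, ...) {
  cat("Term                incl. prob mean (sd)   estimate (95% CI)\n")
  for (i in seq_len(nrow(x))) {
    est <- if (is.na(x$estimate[i])) "---" else
      sprintf("%.3f (%.3f, %.3f)%s", x$estimate[i], x$ci_lower[i],
              x$ci_upper[i], if (x$well_estimated[i]) " *" else "")
    cat(sprintf("%-18s  %.4f (%.4f)  [%s]  %s\n", x$term[i],
                x$incl_mean[i], x$incl_sd[i], x$classification[i], est))
  }
  cat("Note: * indicates a well estimated variable (95% CI excludes 0).\n")
  invisible(x)
}
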