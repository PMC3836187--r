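#' Latent-mixture model specification
#'
#' Hierarchical Bayesian latent-mixture model of per-subject escalation
#' counts. Each subject i has a baseline escalation logit `beta_i` and an
#' unobserved group `z_i` in {1, 2}; in every non-baseline condition c the
#' escalation logit is `beta_i + theta[z_i, c]`, with group 1's effects
#' constrained negative (decreased escalation) and group 2's positive
#' (increased escalation). Escalation counts are binomial. Baselines carry a
#' Gaussian prior on the logit scale and the group effects half-Gaussian
#' priors with the sign constraint, which identifies the groups and prevents
#' label switching. Inference is by Markov chain Monte Carlo:
#' Metropolis-within-Gibbs on the continuous parameters and an exact Gibbs
#' draw of each `z_i` from its two-point conditional.
#'
#' @param baseline_mean,baseline_sd Gaussian prior on subject baselines
#'   (logit scale).
#' @param effect_sd scale of the half-Gaussian prior on group effects.
#' @param chains number of MCMC chains.
#' @param iter draws per chain (including burn-in).
#' @param burn_in draws discarded per chain.
#' @param proposal_sd random-walk proposal standard deviation.
#' @param rhat_threshold split-chain convergence diagnostic threshold above
#'   which a warning is issued (reported, not fatal).
#' @return a list of class `mixture_spec`.
#' @export
mixture_spec <- function(baseline_mean = 0, baseline_sd = 1.5,
                         effect_sd = 1, chains = 4, iter = 5000,
                         burn_in = 2000, proposal_sd = 0.25,
                         rhat_threshold = 1.01) {
  stopifnot(baseline_sd > 0, effect_sd > 0, iter > burn_in, chains >= 1,
            proposal_sd > 0)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 effect_sd = effect_sd, chains = chains, iter = iter,
                 burn_in = burn_in, proposal_sd = proposal_sd,
                 rhat_threshold = rhat_threshold),
            class = "mixture_spec")
}

.mixture_shape <- function(data, baseline_condition) {
  need <- c("subject", "condition", "k_escalate", "n_trials")
  if (!all(need %in% names(data)))
    stop("data needs columns ", paste(need, collapse = ", "))
  stopifnot(all(data$k_escalate >= 0), all(data$k_escalate <= data$n_trials))
  subjects <- sort(unique(data$subject))
  conds <- unique(data$condition)
  if (!baseline_condition %in% conds)
    stop(sprintf("no '%s' condition in the data", baseline_condition))
  conds <- c(baseline_condition, sort(setdiff(conds, baseline_condition)))
  if (length(conds) < 2)
    stop("need at least one non-baseline condition")
  grab <- function(col) {
    m <- matrix(NA_real_, length(subjects), length(conds),
                dimnames = list(subjects, conds))
    for (r in seq_len(nrow(data)))
      m[as.character(data$subject[r]), as.character(data$condition[r])] <-
        data[[col]][r]
    if (anyNA(m)) stop("every subject needs every condition exactly once")
    m
  }
  list(K = grab("k_escalate"), N = grab("n_trials"),
       subjects = subjects, conditions = conds)
}

#' Log posterior density of the latent-mixture model
#'
#' Direct evaluation of the unnormalized log posterior for a complete
#' parameter set: binomial likelihood with
#' `logit(p) = baseline + effect[z, cond]` (effect 0 at baseline), Gaussian
#' prior on baselines, half-Gaussian sign-constrained priors on effects,
#' and a uniform prior over group memberships.
#'
#' @param params list with `baseline` (per subject), `effect`
#'   (2 x n conditions-1 matrix, group 1 negative, group 2 positive) and
#'   `z` (per-subject group index in 1:2).
#' @param data data frame with columns `subject`, `condition`,
#'   `k_escalate`, `n_trials`.
#' @param spec a [mixture_spec()].
#' @param baseline_condition label of the baseline condition.
#' @return scalar log density (`-Inf` if the sign constraint is violated).
#' @export
mixture_logpost <- function(params, data, spec = mixture_spec(),
                            baseline_condition = "baseline") {
  sh <- .mixture_shape(data, baseline_condition)
  beta <- params$baseline
  theta <- params$effect
  z <- params$z
  if (!all(z %in% 1:2) || !all(is.finite(beta)) || !all(is.finite(theta)))
    stop("invalid parameter values")
  if (any(theta[1, ] >= 0) || any(theta[2, ] <= 0)) return(-Inf)
  lp <- sum(stats::dnorm(beta, spec$baseline_mean, spec$baseline_sd,
                         log = TRUE)) +
    sum(stats::dnorm(theta, 0, spec$effect_sd, log = TRUE))
  ll <- sum(stats::dbinom(sh$K[, 1], sh$N[, 1], stats::plogis(beta),
                          log = TRUE))
  for (j in seq_len(ncol(sh$K) - 1))
    ll <- ll + sum(stats::dbinom(sh$K[, j + 1], sh$N[, j + 1],
                                 stats::plogis(beta + theta[cbind(z, j)]),
                                 log = TRUE))
  lp + ll
}

.run_chain <- function(sh, spec, stream, prior_only = FALSE) {
  K <- sh$K
  N <- sh$N
  ns <- nrow(K)
  nj <- ncol(K) - 1
  psd <- spec$proposal_sd
  kept <- spec$iter - spec$burn_in
  out_beta <- matrix(NA_real_, kept, ns)
  out_theta <- array(NA_real_, c(kept, 2, nj))
  out_z <- matrix(NA_integer_, kept, ns)

  ll_base <- function(beta) {
    if (prior_only) return(rep(0, ns))
    stats::dbinom(K[, 1], N[, 1], stats::plogis(beta), log = TRUE)
  }
  # per-subject treatment log likelihood under group effects th[z, ]
  ll_treat <- function(beta, zz, theta) {
    if (prior_only) return(rep(0, ns))
    out <- numeric(ns)
    for (j in seq_len(nj))
      out <- out + stats::dbinom(K[, j + 1], N[, j + 1],
                                 stats::plogis(beta + theta[cbind(zz, j)]),
                                 log = TRUE)
    out
  }

  with_stream(stream, {
    beta <- if (prior_only) stats::rnorm(ns, spec$baseline_mean,
                                         spec$baseline_sd)
            else stats::qlogis((K[, 1] + 0.5) / (N[, 1] + 1)) +
              stats::rnorm(ns, 0, 0.1)
    theta <- rbind(-abs(stats::rnorm(nj, 0, 0.5)) - 0.1,
                   abs(stats::rnorm(nj, 0, 0.5)) + 0.1)
    z <- sample(1:2, ns, replace = TRUE)
    for (it in seq_len(spec$iter)) {
      # subject baselines: independent random-walk Metropolis, vectorized
      prop <- beta + stats::rnorm(ns, 0, psd)
      logr <- ll_base(prop) + ll_treat(prop, z, theta) +
        stats::dnorm(prop, spec$baseline_mean, spec$baseline_sd,
                     log = TRUE) -
        ll_base(beta) - ll_treat(beta, z, theta) -
        stats::dnorm(beta, spec$baseline_mean, spec$baseline_sd, log = TRUE)
      take <- log(stats::runif(ns)) < logr
      beta[take] <- prop[take]
      # group effects: random-walk Metropolis respecting the sign constraint
      for (g in 1:2) for (j in seq_len(nj)) {
        cur <- theta[g, j]
        prop_t <- cur + stats::rnorm(1, 0, psd)
        if ((g == 1 && prop_t >= 0) || (g == 2 && prop_t <= 0)) next
        sel <- z == g
        llc <- if (prior_only || !any(sel)) c(0, 0) else {
          pc <- stats::plogis(beta[sel] + cur)
          pp <- stats::plogis(beta[sel] + prop_t)
          c(sum(stats::dbinom(K[sel, j + 1], N[sel, j + 1], pp, log = TRUE)),
            sum(stats::dbinom(K[sel, j + 1], N[sel, j + 1], pc, log = TRUE)))
        }
        logr_t <- llc[1] + stats::dnorm(prop_t, 0, spec$effect_sd,
                                        log = TRUE) -
          llc[2] - stats::dnorm(cur, 0, spec$effect_sd, log = TRUE)
        if (log(stats::runif(1)) < logr_t) theta[g, j] <- prop_t
      }
      # group memberships: exact Gibbs draw from the two-point conditional
      l1 <- ll_treat(beta, rep(1L, ns), theta)
      l2 <- ll_treat(beta, rep(2L, ns), theta)
      p2 <- 1 / (1 + exp(l1 - l2))
      z <- 1L + (stats::runif(ns) < p2)
      if (it > spec$burn_in) {
        k <- it - spec$burn_in
        out_beta[k, ] <- beta
        out_theta[k, , ] <- theta
        out_z[k, ] <- z
      }
    }
  })
  list(beta = out_beta, theta = out_theta, z = out_z)
}

.split_rhat <- function(mat) {
  # mat: draws x chains; split each chain in half
  half <- floor(nrow(mat) / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[half + seq_len(half), , drop = FALSE])
  m <- ncol(sub)
  n <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical latent-mixture model of escalation
#'
#' Runs the seeded MCMC sampler described in [mixture_spec()] and summarizes
#' the posterior: per-subject group probabilities, the posterior mean group
#' index with its 95% credible interval (the quantity plotted per subject in
#' the study's group-identity figure), and baseline/effect posterior means.
#'
#' @param data data frame with columns `subject`, `condition`, `k_escalate`,
#'   `n_trials`; every subject must have a baseline condition.
#' @param spec a [mixture_spec()].
#' @param seed integer seed; the fit is fully reproducible given it.
#' @param baseline_condition label of the baseline condition.
#' @param prior_only if `TRUE` the likelihood is switched off and the
#'   sampler explores the prior (used to validate the sampler against the
#'   hyperprior moments).
#' @return an object of class `escalation_mixture` with components
#'   `subjects` (per-subject posterior summary data frame), `effects`
#'   (posterior means/intervals of the group effects), `draws`, `rhat`,
#'   `spec` and `data`.
#' @export
fit_escalation_mixture <- function(data, spec = mixture_spec(), seed = 1,
                                   baseline_condition = "baseline",
                                   prior_only = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"))
  sh <- .mixture_shape(data, baseline_condition)
  streams <- stream_split(seed, paste0("chain", seq_len(spec$chains)))
  chains <- lapply(streams, function(s) .run_chain(sh, spec, s, prior_only))
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  z <- do.call(rbind, lapply(chains, `[[`, "z"))
  theta <- do.call(abind1, lapply(chains, `[[`, "theta"))
  ns <- length(sh$subjects)
  nj <- length(sh$conditions) - 1

  subjects <- data.frame(
    subject = sh$subjects,
    p_decrease = colMeans(z == 1),
    p_increase = colMeans(z == 2),
    mean_group = colMeans(z),
    group_lo = apply(z, 2, stats::quantile, 0.025, names = FALSE),
    group_hi = apply(z, 2, stats::quantile, 0.975, names = FALSE),
    baseline_mean = colMeans(beta),
    baseline_lo = apply(beta, 2, stats::quantile, 0.025, names = FALSE),
    baseline_hi = apply(beta, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL)

  effects <- expand.grid(group = 1:2,
                         condition = sh$conditions[-1],
                         stringsAsFactors = FALSE)
  effects$mean <- NA_real_
  effects$lo <- NA_real_
  effects$hi <- NA_real_
  for (r in seq_len(nrow(effects))) {
    g <- effects$group[r]
    j <- match(effects$condition[r], sh$conditions[-1])
    d <- theta[, g, j]
    effects$mean[r] <- mean(d)
    effects$lo[r] <- stats::quantile(d, 0.025, names = FALSE)
    effects$hi[r] <- stats::quantile(d, 0.975, names = FALSE)
  }

  kept <- spec$iter - spec$burn_in
  as_chain_mat <- function(x) matrix(x, kept, spec$chains)
  rhat <- c(
    stats::setNames(vapply(seq_len(ns), function(i)
      .split_rhat(as_chain_mat(beta[, i])), numeric(1)),
      paste0("baseline_", sh$subjects)),
    stats::setNames(vapply(seq_len(2 * nj), function(k) {
      g <- (k - 1) %% 2 + 1
      j <- (k - 1) %/% 2 + 1
      .split_rhat(as_chain_mat(theta[, g, j]))
    }, numeric(1)),
      paste0("effect_g", rep(1:2, nj), "_",
             rep(sh$conditions[-1], each = 2))))
  converged <- all(rhat < spec$rhat_threshold)
  if (!converged)
    warning(sprintf(
      "split-chain diagnostic above %.3g for: %s",
      spec$rhat_threshold,
      paste(names(rhat)[rhat >= spec$rhat_threshold], collapse = ", ")))

  structure(list(subjects = subjects, effects = effects,
                 draws = list(baseline = beta, effect = theta, z = z),
                 rhat = rhat, converged = converged, spec = spec,
                 data = data, conditions = sh$conditions,
                 prior_only = prior_only, seed = seed),
            class = "escalation_mixture")
}

abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1],
                                      numeric(1))), d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.escalation_mixture <- function(x, ...) {
  cat(sprintf("<escalation_mixture: %d subjects, %d conditions, %d chains x %d draws>\n",
              nrow(x$subjects), length(x$conditions), x$spec$chains,
              x$spec$iter))
  lab <- assign_groups(x)
  cat(sprintf("  groups: %d decrease, %d increase, %d unassigned\n",
              sum(lab == "decrease"), sum(lab == "increase"),
              sum(lab == "unassigned")))
  if (!x$converged) cat("  warning: convergence diagnostic above threshold\n")
  invisible(x)
}

#' @export
summary.escalation_mixture <- function(object, ...) {
  out <- object$subjects
  out$label <- assign_groups(object)
  out
}

#' @export
coef.escalation_mixture <- function(object, ...) {
  c(stats::setNames(object$subjects$baseline_mean,
                    paste0("baseline_", object$subjects$subject)),
    stats::setNames(object$effects$mean,
                    paste0("effect_g", object$effects$group, "_",
                           object$effects$condition)))
}

#' Plot posterior group affiliation per subject
#'
#' One point per subject: the posterior mean group index (1 = decreased
#' escalation relative to baseline, 2 = increased) with its 95% credible
#' interval, colored by the assigned group.
#'
#' @param x an [fit_escalation_mixture()] result.
#' @param threshold assignment threshold passed to [assign_groups()].
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.escalation_mixture <- function(x, threshold = 0.75, ...) {
  s <- x$subjects
  lab <- assign_groups(x, threshold)
  col <- c(decrease = "forestgreen", increase = "firebrick",
           unassigned = "grey50")[lab]
  n <- nrow(s)
  graphics::plot(seq_len(n), s$mean_group, ylim = c(0.9, 2.1), pch = 19,
                 col = col, xlab = "subject", xaxt = "n",
                 ylab = "posterior mean group (1 = decrease, 2 = increase)",
                 ...)
  graphics::axis(1, at = seq_len(n), labels = s$subject)
  graphics::segments(seq_len(n), s$group_lo, seq_len(n), s$group_hi,
                     col = col)
  graphics::abline(h = 1.5, lty = 3)
  invisible(x)
}

#' Assign subjects to mixture groups
#'
#' Labels each subject `decrease` or `increase` when the posterior
#' probability of the corresponding group exceeds `threshold`, and
#' `unassigned` (the relatively unbiased middle ground) otherwise.
#'
#' @param fit an [fit_escalation_mixture()] result.
#' @param threshold posterior probability required for assignment.
#' @return character vector of labels, one per subject.
#' @export
assign_groups <- function(fit, threshold = 0.75) {
  stopifnot(inherits(fit, "escalation_mixture"))
  ifelse(fit$subjects$p_decrease > threshold, "decrease",
         ifelse(fit$subjects$p_increase > threshold, "increase",
                "unassigned"))
}

#' Generate synthetic subjects for parameter recovery
#'
#' Draws per-subject, per-condition escalation counts from the latent
#' mixture's generative process: `k ~ Binomial(n, plogis(baseline +
#' effect))`, with effect 0 in the baseline condition and the group's
#' signed effect elsewhere. Stands in for the unpublished human dataset in
#' recovery studies.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject and condition.
#' @param group_assignment integer vector in {1, 2} per subject (group 1
#'   decreases escalation, group 2 increases).
#' @param baselines per-subject baseline logits; `NULL` draws them from
#'   `N(0, baseline_sd)`.
#' @param effect_size absolute condition effect in logits; group 1 gets
#'   `-effect_size`, group 2 `+effect_size`.
#' @param baseline_sd standard deviation used when drawing baselines.
#' @param conditions condition labels; the first is the baseline.
#' @param seed integer seed.
#' @return list with `data` (a data frame as accepted by
#'   [fit_escalation_mixture()]) and `truth` (the generating latents).
#' @export
synth_subjects <- function(n_subjects = 8, n_trials = 100,
                           group_assignment = rep(1:2, each = n_subjects / 2),
                           baselines = NULL, effect_size = 1.5,
                           baseline_sd = 0.5,
                           conditions = c("baseline", "treatment"),
                           seed = 1) {
  stopifnot(length(group_assignment) == n_subjects,
            all(group_assignment %in% 1:2), length(conditions) >= 2)
  stream <- rng_stream(seed)
  if (is.null(baselines))
    baselines <- with_stream(stream,
                             stats::rnorm(n_subjects, 0, baseline_sd))
  stopifnot(length(baselines) == n_subjects)
  effects <- c(-effect_size, effect_size)
  rows <- list()
  for (i in seq_len(n_subjects)) for (cond in conditions) {
    eff <- if (cond == conditions[1]) 0 else effects[group_assignment[i]]
    p <- stats::plogis(baselines[i] + eff)
    k <- with_stream(stream, stats::rbinom(1, n_trials, p))
    rows[[length(rows) + 1]] <- data.frame(
      subject = sprintf("s%02d", i), condition = cond,
      k_escalate = k, n_trials = n_trials)
  }
  list(data = do.call(rbind, rows),
       truth = list(group = group_assignment, baselines = baselines,
                    effect_size = effect_size, conditions = conditions))
}

#' Export a simulated session as a choice dataset row
#'
#' Collapses a matrix-game session into per-player escalation counts under a
#' condition label, in the format accepted by [fit_escalation_mixture()]
#' (one row per player).
#'
#' @param session a [run_session()] result for Hawk-Dove or Chicken.
#' @param condition condition label for these counts.
#' @param subjects length-2 subject labels for the two seats.
#' @return data frame with columns `subject`, `condition`, `k_escalate`,
#'   `n_trials`.
#' @export
session_choice_data <- function(session, condition = "baseline",
                                subjects = c("p1", "p2")) {
  rec <- session$records
  if (!"round" %in% names(rec))
    stop("choice datasets come from matrix-game sessions")
  risky <- .game_actions(rec$game[1])[["risky"]]
  data.frame(subject = subjects, condition = condition,
             k_escalate = c(sum(rec$action_p1 == risky),
                            sum(rec$action_p2 == risky)),
             n_trials = nrow(rec))
}
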