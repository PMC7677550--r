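# Minimal tree-structured Parzen estimator for low-dimensional
# hyperparameter search. Dimensions are treated independently on a
# transformed unit scale (log for *num/*int "log" types), with Gaussian
# kernel density estimates over the good/bad trial split.

to_unit <- function(x, def) {
  if (def$type %in% c("lognum", "logint")) {
    (log(x) - log(def$low)) / (log(def$high) - log(def$low))
  } else {
    (x - def$low) / (def$high - def$low)
  }
}

from_unit <- function(u, def) {
  u <- pmin(pmax(u, 0), 1)
  x <- if (def$type %in% c("lognum", "logint")) {
    exp(log(def$low) + u * (log(def$high) - log(def$low)))
  } else {
    def$low + u * (def$high - def$low)
  }
  if (def$type %in% c("int", "logint")) {
    x <- pmin(pmax(round(x), def$low), def$high)
  }
  x
}

sample_prior <- function(space) {
  lapply(space, function(def) from_unit(runif(1), def))
}

kde_logdens <- function(u, obs) {
  if (!length(obs)) return(rep(0, length(u)))
  bw <- max(1.06 * sd(obs) * length(obs)^(-0.2), 0.08)
  vapply(u, function(ui) log(mean(dnorm(ui, obs, bw)) + 1e-12), numeric(1))
}

# objective: function(params list) -> numeric score (minimized)
tpe_optimize <- function(objective, space, n_trials, seed,
                         n_startup = 15, gamma = 0.25, n_candidates = 24) {
  set.seed(seed)
  hist_params <- vector("list", n_trials)
  scores <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    if (t <= n_startup) {
      p <- sample_prior(space)
    } else {
      sc <- scores[seq_len(t - 1)]
      n_good <- max(1, ceiling(gamma * (t - 1)))
      good <- order(sc)[seq_len(n_good)]
      p_prev <- hist_params[seq_len(t - 1)]
      p <- list()
      for (nm in names(space)) {
        def <- space[[nm]]
        u_all <- vapply(p_prev, function(q) to_unit(q[[nm]], def), numeric(1))
        u_good <- u_all[good]
        u_bad <- u_all[-good]
        # candidates drawn around good observations
        bw <- max(1.06 * sd(u_good) * length(u_good)^(-0.2), 0.08)
        cand <- rnorm(n_candidates, sample(u_good, n_candidates, replace = TRUE), bw)
        cand <- pmin(pmax(cand, 0), 1)
        ratio <- kde_logdens(cand, u_good) - kde_logdens(cand, u_bad)
        p[[nm]] <- from_unit(cand[which.max(ratio)], def)
      }
    }
    hist_params[[t]] <- p
    scores[t] <- objective(p)
  }
  best <- which.min(scores)
  trials <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    data.frame(trial = t, as.data.frame(hist_params[[t]]), score = scores[t])
  }))
  list(best = hist_params[[best]], best_score = scores[best], trials = trials)
}
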