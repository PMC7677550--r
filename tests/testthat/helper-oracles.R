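# Independent brute-force oracles, kept deliberately naive and separate
# from the package implementations they check.

oracle_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

oracle_sdnn <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  sqrt(s / (length(x) - 1))
}

oracle_hrvti <- function(x, bw = 1000 / 128) {
  bins <- floor(x / bw)
  counts <- sapply(unique(bins), function(b) sum(bins == b))
  length(x) / max(counts)
}

oracle_hr <- function(x) 60000 / (sum(x) / length(x))

# single-pass 3-SD rule applied literally
oracle_clean <- function(x) {
  m <- mean(x); s <- sd(x)
  flag <- abs(x - m) > 3 * s
  out <- x
  good <- which(!flag)
  for (i in which(flag)) {
    lo <- suppressWarnings(max(good[good < i]))
    hi <- suppressWarnings(min(good[good > i]))
    out[i] <- if (!is.finite(lo)) x[hi]
      else if (!is.finite(hi)) x[lo]
      else x[lo] + (x[hi] - x[lo]) * (i - lo) / (hi - lo)
  }
  list(values = out, flags = flag)
}

random_nn <- function(n, seed) {
  set.seed(seed)
  800 + cumsum(rnorm(n, 0, 15)) + rnorm(n, 0, 30)
}

# conditional expectation of one boosted tree given feature subset S
# (cover-weighted traversal), used by the exact-Shapley oracle
tree_cond_exp <- function(tr, x, S, j = 1) {
  if (tr$feature[j] < 0) return(tr$value[j])
  fi <- tr$feature[j] + 1
  l <- tr$left[j] + 1; r <- tr$right[j] + 1
  if (fi %in% S) {
    if (x[fi] < tr$threshold[j]) tree_cond_exp(tr, x, S, l)
    else tree_cond_exp(tr, x, S, r)
  } else {
    (tr$cover[l] * tree_cond_exp(tr, x, S, l) +
       tr$cover[r] * tree_cond_exp(tr, x, S, r)) / tr$cover[j]
  }
}

oracle_shapley <- function(model, x) {
  p <- length(model$feature_names)
  f_S <- function(S) {
    model$base_score +
      sum(vapply(model$trees, function(tr) tree_cond_exp(tr, x, S), numeric(1)))
  }
  vapply(seq_len(p), function(i) {
    others <- setdiff(seq_len(p), i)
    tot <- 0
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(integer(0)) else combn(others, k, simplify = FALSE)
      for (S in combs) {
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        tot <- tot + w * (f_S(c(S, i)) - f_S(S))
      }
    }
    tot
  }, numeric(1))
}

# minimal subject list for build_feature_table-style inputs
scripted_subject <- function(id, er_traj, ea_traj, er_feet = NULL, ea_feet = NULL) {
  mk <- function(traj, feet, scen) {
    session_recording(id, scen, traj, foot_tracks = feet,
                      duration = max(traj$t))
  }
  list(subject_id = id, stai_t = 40,
       sessions = list(empty_room = mk(er_traj, er_feet, "empty_room"),
                       elevated_alley = mk(ea_traj, ea_feet, "elevated_alley")))
}

# stationary trajectory at a point
pin_traj <- function(x, y, duration = 30, rate = 30) {
  tt <- seq(0, duration, by = 1 / rate)
  data.frame(t = tt, x = x, y = y, z = 1.7, yaw = 90)
}
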