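# Brute-force oracles, written independently of the package's production
# code paths: naive double loops over atom pairs, direct RMSD sums, and
# hypergeometric enumeration for the exact test.

oracle_pairs <- function(probe, env, excl = NULL) {
  # all probe x env heavy-atom pairs with distance and radius sum,
  # exclusion applied by key lookup; plain loops, preallocated vectors
  exk <- if (!is.null(excl) && nrow(excl)) {
    paste(excl[[1]], excl[[2]], sep = "~")
  } else character(0)
  np <- nrow(probe); ne <- nrow(env)
  key <- character(np * ne); d <- numeric(np * ne); rsum <- numeric(np * ne)
  m <- 0L
  for (i in seq_len(np)) {
    ki <- paste0(probe$resno[i], ":", probe$name[i])
    for (j in seq_len(ne)) {
      kj <- paste0(env$resno[j], ":", env$name[j])
      if (ki == kj) next
      kij <- paste(ki, kj, sep = "~")
      if (kij %in% exk) next
      m <- m + 1L
      key[m] <- kij
      d[m] <- sqrt((probe$x[i] - env$x[j])^2 + (probe$y[i] - env$y[j])^2 +
                     (probe$z[i] - env$z[j])^2)
      rsum[m] <- probe$vdw[i] + env$vdw[j]
    }
  }
  data.frame(key = key[seq_len(m)], d = d[seq_len(m)],
             rsum = rsum[seq_len(m)], stringsAsFactors = FALSE)
}

oracle_hbond_keys <- function(donors, acceptors, max_d = 3.5,
                              min_ang = 90) {
  out <- character(0)
  for (i in seq_len(nrow(donors))) {
    for (j in seq_len(nrow(acceptors))) {
      if (donors$resno[i] == acceptors$resno[j]) next
      dv <- c(acceptors$x[j] - donors$x[i], acceptors$y[j] - donors$y[i],
              acceptors$z[j] - donors$z[i])
      dist <- sqrt(sum(dv^2))
      if (dist > max_d || dist < 1e-6) next
      av <- c(donors$ax[i] - donors$x[i], donors$ay[i] - donors$y[i],
              donors$az[i] - donors$z[i])
      cosang <- sum(av * dv) / (sqrt(sum(av^2)) * dist)
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang < min_ang) next
      out <- c(out, paste0(donors$resno[i], ":", donors$name[i], "~",
                           acceptors$resno[j], ":", acceptors$name[j]))
    }
  }
  sort(out)
}

oracle_clash_keys <- function(probe, env, threshold = 0.4, excl = NULL) {
  p <- oracle_pairs(probe, env, excl)
  sort(p$key[p$rsum - p$d > threshold])
}

oracle_contact_keys <- function(probe, env, shell = 0.5, threshold = 0.4,
                                excl = NULL) {
  p <- oracle_pairs(probe, env, excl)
  sort(p$key[p$rsum - p$d <= threshold & p$d <= p$rsum + shell])
}

oracle_rmsd <- function(a, b) {
  # direct pairwise-distance RMSD, no linear algebra shared with kabsch
  stopifnot(nrow(a) == nrow(b))
  s <- 0
  for (i in seq_len(nrow(a))) {
    s <- s + sum((a[i, ] - b[i, ])^2)
  }
  sqrt(s / nrow(a))
}

oracle_fisher_p <- function(tab) {
  # two-sided Fisher p by full hypergeometric enumeration over all tables
  # with the observed margins
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_atom_set <- function(n, span = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    name = paste0("C", seq_len(n)),
    resno = seq_len(n),
    x = runif(n, 0, span), y = runif(n, 0, span), z = runif(n, 0, span),
    vdw = sample(c(1.52, 1.55, 1.70, 1.80), n, replace = TRUE),
    is_hydrogen = rep(FALSE, n),
    stringsAsFactors = FALSE)
}

clash_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste0(df$probe_resno, ":", df$probe_name, "~",
              df$env_resno, ":", df$env_name))
}
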