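# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; no stored data.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n = 80L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# quick mutant-only distribution: random +1 insertions and deletions
rand_mutant_dist <- function(seed = 1L, n_del = 8L, n_ins = 2L,
                             guide_id = "g") {
  set.seed(seed)
  lens <- sample(1:15, n_del)
  starts <- -sample(0:5, n_del, replace = TRUE)
  ins_b <- sample(BASES, n_ins)
  f <- stats::runif(n_del + n_ins)
  outcome_dist(kind = c(rep("deletion", n_del), rep("insertion", n_ins)),
               length = c(lens, rep(1L, n_ins)),
               frequency = f / sum(f),
               del_start = c(starts, rep(NA, n_ins)),
               ins_bases = c(rep(NA, n_del), ins_b),
               guide_id = guide_id)
}

# random activity model built directly (no file round-trip)
rand_activity_model <- function(seed = 1L, n1 = 12L, n2 = 15L) {
  set.seed(seed)
  p1 <- sample(1:35, n1)
  k1 <- sample(BASES, n1, replace = TRUE)
  p2 <- sample(1:34, n2)
  k2 <- paste0(sample(BASES, n2, TRUE), sample(BASES, n2, TRUE))
  w <- stats::rnorm(n1 + n2, 0, 0.1)
  names(w) <- paste0(c(p1, p2), ":", c(k1, k2))
  w <- w[!duplicated(names(w))]
  structure(list(intercept = stats::rnorm(1, 0.4, 0.1), weights = w,
                 scale_lo = 0, scale_hi = 1),
            class = "activity_model")
}

# oracle: brute-force feature-indicator dot product over the model table
oracle_activity <- function(context35, model) {
  lp <- model$intercept
  for (nm in names(model$weights)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    pos <- as.integer(parts[1])
    kmer <- parts[2]
    if (substr(context35, pos, pos + nchar(kmer) - 1L) == kmer)
      lp <- lp + model$weights[[nm]]
  }
  min(max(100 * (lp - model$scale_lo) / (model$scale_hi - model$scale_lo),
          0), 100)
}

# oracle: smallest deletion length L at which cumulative mass over +1
# insertions plus deletions of length <= L first exceeds the threshold
oracle_lstar <- function(reference, threshold = 0.99) {
  acc <- 0
  for (i in seq_len(nrow(reference)))
    if (reference$kind[i] == "insertion" && reference$length[i] == 1L)
      acc <- acc + reference$frequency[i]
  for (L in 1:200) {
    for (i in seq_len(nrow(reference)))
      if (reference$kind[i] == "deletion" && reference$length[i] == L)
        acc <- acc + reference$frequency[i]
    if (acc > threshold) return(L)
  }
  NA_integer_
}

# oracle: enumerate all protospacer+PAM hits on one orientation of a
# sequence by sliding a 23-nt window; returns between-base cut coords
oracle_scan_one_strand <- function(seq) {
  n <- nchar(seq)
  hits <- list()
  if (n >= 23L) {
    for (a in 1:(n - 22L)) {
      w <- substr(seq, a, a + 22L)
      if (substr(w, 22L, 23L) == "GG") {
        cut <- a + 16L
        if (cut >= 40L && n - cut >= 40L)
          hits[[length(hits) + 1L]] <- list(proto = substr(w, 1L, 20L),
                                            pam = substr(w, 21L, 23L),
                                            cut = cut)
      }
    }
  }
  hits
}

oracle_scan <- function(seq) {
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- oracle_scan_one_strand(seq)
  rev <- oracle_scan_one_strand(rc)
  plus <- lapply(fwd, function(h) c(h, strand = "+", cut_fwd = h$cut))
  minus <- lapply(rev, function(h) c(h, strand = "-", cut_fwd = n - h$cut))
  c(plus, minus)
}

# oracle: unique edited sequences reachable by deletions spanning the cut
oracle_spanning_deletions <- function(context, max_len = 30L) {
  n <- nchar(context)
  cut <- n %/% 2L
  prods <- character(0)
  for (L in 1:max_len) {
    for (s in (-L):0) {
      p <- cut + s + 1L
      if (p < 1L || p + L - 1L > n) next
      edited <- paste0(substr(context, 1L, p - 1L),
                       substr(context, p + L, n))
      prods <- c(prods, paste0(L, "|", edited))
    }
  }
  unique(prods)
}

# oracle: textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# curated prediction/observation pairs from a gen_panel output
curated_pairs <- function(panel) {
  lapply(panel, function(p) {
    o <- normalize_observed(p$obs_raw)
    list(pred = curate_to_reference_classes(p$pred, p$pred),
         obs = curate_to_reference_classes(o, p$pred))
  })
}

# inflate the +1 insertion mass of a mutant-only distribution by delta,
# rescaling deletions so the result stays on the simplex
inflate_plus1 <- function(dist, delta = 0.05) {
  f <- dist$frequency
  ins <- dist$kind == "insertion" & dist$length == 1L
  it <- sum(f[ins])
  stopifnot(it > 0, it + delta < 1)
  f[ins] <- f[ins] * (it + delta) / it
  f[!ins] <- f[!ins] * (1 - it - delta) / (1 - it)
  outcome_dist(kind = dist$kind, length = dist$length, frequency = f,
               del_start = dist$del_start, ins_bases = dist$ins_bases,
               mh = dist$mh, guide_id = attr(dist, "guide_id"),
               source = "predicted", method = "inflated")
}
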