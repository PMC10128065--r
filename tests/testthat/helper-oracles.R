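# Independent oracles used across the suite. These deliberately take a
# different computational route than the package functions they check.

# Evaluate a step expression string by textual substitution into an R
# logical expression: KO ids present in `kos` become TRUE, others FALSE,
# AND/OR become &/|. Independent of the package's recursive-descent parser
# and tree evaluator.
oracleEvalStepText <- function(text, kos) {
  ids <- unique(regmatches(text, gregexpr("K[0-9]{5}", text))[[1L]])
  expr <- text
  for (id in ids)
    expr <- gsub(id, if (id %in% kos) "TRUE" else "FALSE", expr, fixed = TRUE)
  expr <- gsub("\\bAND\\b", "&", expr)
  expr <- gsub("\\bOR\\b", "|", expr)
  eval(parse(text = expr))
}

# brute-force completeness from step texts
oracleCompleteness <- function(rule, kos) {
  sat <- vapply(rule@stepText, oracleEvalStepText, logical(1L), kos = kos)
  sum(sat) / length(sat)
}

# naive two-pass family aggregation: per sample, pool sub-threshold ASVs
# into "Other", then sum the rest by family, one cell at a time
oracleAggregateFamilies <- function(ra, fam, threshold) {
  famLevels <- sort(unique(fam))
  out <- matrix(0, nrow(ra), length(famLevels) + 1L,
                dimnames = list(rownames(ra), c(famLevels, "Other")))
  for (s in seq_len(nrow(ra))) for (a in seq_len(ncol(ra))) {
    v <- ra[s, a]
    if (v < threshold) out[s, "Other"] <- out[s, "Other"] + v
    else out[s, fam[a]] <- out[s, fam[a]] + v
  }
  out
}

# exhaustive-permutation PERMANOVA oracle: pseudo-F recomputed from the
# Gower-centered inner-product matrix (a different algebraic route than
# the package's pairwise-sum formulation), p by full enumeration
oraclePermanovaF <- function(d, grp) {
  d <- as.matrix(d); N <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(N) - matrix(1 / N, N, N)
  G <- J %*% A %*% J
  H <- model.matrix(~ factor(grp))
  Hat <- H %*% solve(crossprod(H)) %*% t(H)
  a <- length(unique(grp))
  ssB <- sum(diag(Hat %*% G))
  ssW <- sum(diag((diag(N) - Hat) %*% G))
  (ssB / (a - 1)) / (ssW / (N - a))
}

oraclePerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oraclePerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# reference single-linkage clustering by transitive closure of the
# thresholded adjacency matrix (matrix-power reachability)
oracleClusterCount <- function(m, threshold) {
  adj <- (!is.na(m) & m >= threshold) | diag(nrow(m)) == 1
  reach <- adj
  for (i in seq_len(nrow(m))) reach <- (reach %*% adj) > 0
  length(unique(apply(reach, 1L, function(r) paste(which(r), collapse = ","))))
}

randomKoSet <- function(n, pool) sample(pool, min(n, length(pool)))
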