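# Clone deconvolution from bulk variant allele frequencies under the
# CNA-free heterozygous diploid model V = (1/2) f^T M: f is the cancer-cell
# fraction of each clone in a sample, M the binary clone genotype matrix.

#' Observed variant allele frequencies from a mutation profile
#'
#' @param profile a validated `mutation_profile`
#' @return list with `V` (SNVs x samples, alt/(alt+ref), NA where total
#'   depth is 0) and `depth` (total read counts).
#' @export
compute_vaf <- function(profile) {
  depth <- profile$ref_count + profile$alt_count
  V <- profile$alt_count / depth
  V[depth == 0] <- NA_real_
  list(V = V, depth = depth)
}

#' Estimate clone frequencies in one sample
#'
#' Solves the depth-weighted constrained least-squares problem
#' \deqn{\min_f \lVert W (\tfrac12 M^T f - V_s) \rVert^2,\quad f \ge 0,\ \sum f \le 1}
#' with \eqn{W = \mathrm{diag}(\sqrt{depth})}; the unassigned remainder
#' \eqn{1 - \sum f} is the normal-cell fraction. Missing entries (depth 0)
#' are dropped. The inequality is handled through a non-negative slack
#' variable and the solver is a deterministic active-set NNLS; among
#' minimizers of a rank-deficient system a tiny ridge selects the
#' smallest-norm solution (documented tie-break).
#'
#' @param M binary clone genotype matrix (clones x SNVs)
#' @param V_s one sample's VAF vector (length = SNVs; NAs allowed)
#' @param depth_s matching total read counts (default: uniform)
#' @return non-negative frequency vector over clones, sum at most 1
#' @export
estimate_frequencies <- function(M, V_s, depth_s = rep(1, length(V_s))) {
  stopifnot(nrow(M) >= 1, ncol(M) == length(V_s))
  ok <- !is.na(V_s) & depth_s > 0
  if (!any(ok)) return(stats::setNames(numeric(nrow(M)), rownames(M)))
  A0 <- t(M[, ok, drop = FALSE]) / 2
  w <- sqrt(depth_s[ok])
  w <- w / mean(w)                       # scale-free weighting
  k <- nrow(M)
  lambda <- 1e4
  ridge <- 1e-8
  A <- rbind(A0 * w, rep(lambda, k), diag(sqrt(ridge), k))
  A <- cbind(A, c(rep(0, sum(ok)), lambda, rep(0, k)))  # slack column
  b <- c(V_s[ok] * w, lambda, numeric(k))
  z <- nnls_fit(A, b)
  f <- z[seq_len(k)]
  f[f < 1e-12] <- 0
  if (sum(f) > 1) f <- f / sum(f)        # numerical guard only
  stats::setNames(f, rownames(M))
}

# depth-weighted total squared residual of a (M, f) fit against V
fit_residual <- function(M, f, V, depth) {
  pred <- f %*% M / 2                     # samples x SNVs
  resid <- t(pred) - V
  sum(depth * resid^2, na.rm = TRUE)
}

# binomial goodness-of-fit: sum over entries of (alt - depth*vhat)^2 /
# (depth*vhat*(1-vhat)), vhat clamped away from 0/1 by the error rate
fit_chisq <- function(M, f, alt, depth, err = 0.001) {
  vhat <- t(f %*% M / 2)
  vhat <- pmin(pmax(vhat, err), 1 - err)
  ok <- depth > 0
  sum(((alt - depth * vhat)^2 / (depth * vhat * (1 - vhat)))[ok])
}

# Backward elimination of clones by a BIC-like rule: removing a clone frees
# n_samples frequency parameters; the removal is accepted when the binomial
# chi-square grows by less than n_samples * log(n_entries). Spurious union /
# split-artifact candidates are absorbed by the remaining clones; removing a
# real clone degrades the fit by orders of magnitude more than the penalty.
prune_clones_bic <- function(M, fit_freqs, alt, depth, err = 0.001) {
  n_entries <- sum(depth > 0)
  penalty <- ncol(alt) * log(n_entries)
  repeat {
    if (nrow(M) <= 1) break
    f <- fit_freqs(M)
    chi_full <- fit_chisq(M, f, alt, depth, err)
    delta <- vapply(seq_len(nrow(M)), function(k) {
      Mk <- M[-k, , drop = FALSE]
      fit_chisq(Mk, fit_freqs(Mk), alt, depth, err) - chi_full
    }, 0)
    k <- which.min(delta)
    if (delta[k] < penalty) M <- M[-k, , drop = FALSE] else break
  }
  M
}

# Per-sample presence call for one SNV: enough mutant reads and a one-sided
# binomial test against the sequencing error rate.
presence_matrix <- function(profile, min_alt = 3, err = 0.001, p_cut = 0.01) {
  alt <- profile$alt_count
  depth <- profile$ref_count + alt
  # P(X >= alt) under Binomial(depth, err)
  p <- stats::pbinom(alt - 1L, depth, err, lower.tail = FALSE)
  alt >= min_alt & p < p_cut
}

# Attempt to split one candidate clone whose SNVs show a bimodal VAF pattern
# in some sample: fit 1- vs 2-mean models (exact 1-D k-means via sorted
# split), accept on BIC improvement, and return the implied ancestor genotype
# (the high-VAF subset of the clone's mutations).
propose_split <- function(geno, V, depth, f_col) {
  snvs <- which(geno == 1L)
  if (length(snvs) < 6) return(NULL)
  samples <- which(f_col > 0.05)
  best <- NULL
  for (s in samples) {
    v <- V[snvs, s]
    keep <- !is.na(v)
    if (sum(keep) < 6) next
    v2 <- v[keep]
    o <- order(v2)
    vs <- v2[o]
    n <- length(vs)
    sse1 <- sum((vs - mean(vs))^2)
    bic1 <- n * log(sse1 / n + 1e-12) + log(n)
    bic2_best <- Inf; cut_best <- NA
    for (cut in 3:(n - 3)) {
      lo <- vs[1:cut]; hi <- vs[(cut + 1):n]
      sse2 <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
      bic2 <- n * log(sse2 / n + 1e-12) + 3 * log(n)
      if (bic2 < bic2_best) { bic2_best <- bic2; cut_best <- cut }
    }
    if (is.finite(bic2_best) && bic2_best < bic1 - 2) {
      lo_mean <- mean(vs[1:cut_best]); hi_mean <- mean(vs[(cut_best + 1):n])
      if (hi_mean - lo_mean < 0.04) next   # clusters must be separated
      hi_snvs <- snvs[keep][o][(cut_best + 1):n]
      anc <- integer(length(geno))
      anc[hi_snvs] <- 1L
      best <- anc
      break
    }
  }
  best
}

# Per-SNV genotype refinement: given clone frequencies, re-pick each SNV's
# binary clone-assignment column by exhaustive minimization of the binomial
# chi-square (2^K patterns; skipped for K > max_k). Ties keep the current
# column, then lowest pattern index — deterministic.
refine_genotypes <- function(M, f, alt, depth, err = 0.001, max_k = 12) {
  K <- nrow(M)
  if (K > max_k) return(M)
  pat <- as.matrix(expand.grid(rep(list(0:1), K)))[, K:1, drop = FALSE]
  pred <- pat %*% t(f) / 2                       # patterns x samples
  pred <- pmin(pmax(pred, err), 1 - err)
  n_snv <- ncol(M)
  chi <- matrix(0, n_snv, nrow(pat))
  for (s in seq_len(ncol(alt))) {
    d <- depth[, s]
    ok <- d > 0
    num <- (outer(alt[ok, s], rep(1, nrow(pat))) - outer(d[ok], pred[, s]))^2
    chi[ok, ] <- chi[ok, ] + num / outer(d[ok], pred[, s] * (1 - pred[, s]))
  }
  cur <- apply(t(M), 1, function(col) sum(col * 2^((K - 1):0)) + 1)
  best <- integer(n_snv)
  for (j in seq_len(n_snv)) {
    v <- chi[j, ]
    b <- which.min(v)
    if (v[cur[j]] <= v[b] + 1e-9) b <- cur[j]
    best[j] <- b
  }
  M2 <- t(pat[best, , drop = FALSE])
  storage.mode(M2) <- "integer"
  dimnames(M2) <- dimnames(M)
  M2
}

#' Infer clone genotypes and frequencies from a mutation profile
#'
#' Iterative deconvolution assuming the samples are evolutionarily related:
#' (1) seed candidate clone genotypes by binarizing each sample's SNV
#' presence (mutant-read threshold plus a one-sided binomial test against the
#' sequencing error rate) and merging duplicates; (2) build a
#' maximum-parsimony phylogeny over the candidates and add the reconstructed
#' ancestral genotypes as further candidates; (3) estimate per-sample clone
#' frequencies by constrained least squares; (4) split candidates whose SNV
#' set shows a bimodal VAF pattern within a sample (1- vs 2-component BIC)
#' into a tree-compatible ancestor/descendant pair; (5) drop clones whose
#' frequency stays below `presence_threshold` in every sample. Steps 2-5
#' repeat until the genotype set is stable or `max_iter` is reached; an
#' iteration is only accepted if the depth-weighted reconstruction residual
#' does not increase.
#'
#' @param profile a `mutation_profile` (at least four samples)
#' @param presence_threshold minimum frequency for a clone to be considered
#'   present in a sample (default 0.02, below bulk detection resolution)
#' @param max_iter maximum refinement iterations (default 10)
#' @param min_alt,err,p_cut presence-test parameters (see Details)
#' @return list with `clones` (a `clone_set`: binary `M` clones x SNVs,
#'   `f` samples x clones) and `phylogeny` (the final `clone_phylogeny`).
#' @export
infer_clones <- function(profile, presence_threshold = 0.02, max_iter = 10,
                         min_alt = 3, err = 0.001, p_cut = 0.01) {
  vaf <- compute_vaf(profile)
  V <- vaf$V; depth <- vaf$depth
  pres <- presence_matrix(profile, min_alt, err, p_cut)
  if (!any(pres)) stop("no clonal signal: no SNV passes the presence test in any sample")
  # 1. seed candidates: one genotype per sample (its SNV presence pattern)
  cand <- unique(t(pres) * 1L)                     # samples x SNVs -> rows
  cand <- cand[rowSums(cand) > 0, , drop = FALSE]
  colnames(cand) <- profile$snv_ids
  storage.mode(cand) <- "integer"
  fit_freqs <- function(M) {
    fm <- vapply(seq_along(profile$sample_names), function(s)
      estimate_frequencies(M, V[, s], depth[, s]), numeric(nrow(M)))
    f <- t(matrix(fm, nrow = nrow(M)))
    rownames(f) <- profile$sample_names
    colnames(f) <- rownames(M)
    f
  }
  dedupe <- function(M) {
    M <- M[rowSums(M) > 0, , drop = FALSE]
    M[!duplicated(apply(M, 1, paste, collapse = "")), , drop = FALSE]
  }
  name_clones <- function(M) {
    o <- order(rowSums(M), apply(M, 1, paste, collapse = ""))
    M <- M[o, , drop = FALSE]
    rownames(M) <- paste0("Clone", seq_len(nrow(M)))
    M
  }
  M <- name_clones(dedupe(cand))
  prev_key <- ""
  prev_resid <- Inf
  f <- fit_freqs(M)
  for (it in seq_len(max_iter)) {
    # 2. add MP-ancestral genotypes as candidates
    M_new <- M
    if (nrow(M) >= 2) {
      cp <- clone_phylogeny(M)
      anc <- cp$genotypes[setdiff(seq_len(rtree_n(cp$tree)),
                                  rtree_tips(cp$tree)), , drop = FALSE]
      colnames(anc) <- colnames(M)
      M_new <- rbind(M, anc)
    }
    # 4. bimodal-split candidates
    f_cur <- fit_freqs(name_clones(dedupe(M_new)))
    M_cur <- name_clones(dedupe(M_new))
    for (k in seq_len(nrow(M_cur))) {
      anc <- propose_split(M_cur[k, ], V, depth, f_cur[, k])
      if (!is.null(anc) && sum(anc) > 0) M_new <- rbind(M_new, anc)
    }
    M_new <- name_clones(dedupe(M_new))
    f_new <- fit_freqs(M_new)
    # 5. drop clones never present
    keep <- apply(f_new, 2, max) >= presence_threshold
    if (!any(keep)) keep[which.max(apply(f_new, 2, max))] <- TRUE
    M_new <- name_clones(M_new[keep, , drop = FALSE])
    f_new <- fit_freqs(M_new)
    resid <- fit_residual(M_new, f_new, V, depth)
    if (resid > prev_resid * (1 + 1e-9) + 1e-9) break   # reject, keep previous
    M <- M_new; f <- f_new
    prev_resid <- resid
    key <- paste(apply(M, 1, paste, collapse = ""), collapse = "|")
    if (identical(key, prev_key)) break
    prev_key <- key
  }
  alt <- profile$alt_count
  M <- name_clones(prune_clones_bic(M, fit_freqs, alt, depth, err))
  # alternate genotype refinement and frequency refitting, then prune again
  for (it in 1:2) {
    f <- fit_freqs(M)
    M2 <- name_clones(dedupe(refine_genotypes(M, f, alt, depth, err)))
    if (identical(M2, M)) break
    M <- M2
  }
  M <- name_clones(prune_clones_bic(M, fit_freqs, alt, depth, err))
  f <- fit_freqs(M)
  cp <- clone_phylogeny(M)
  clones <- structure(list(M = M, f = f, clone_names = rownames(M)),
                      class = "clone_set")
  list(clones = clones, phylogeny = cp)
}
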