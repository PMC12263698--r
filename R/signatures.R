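# Single-base-substitution (SBS) channels and branch-specific signature
# refitting. Spectra are 96-vectors over pyrimidine-centered channels; a
# purine-reference mutation is reverse-complemented onto its pyrimidine
# channel before counting.

#' Canonical 96 SBS channel labels
#'
#' Six pyrimidine substitution classes (C>A, C>G, C>T, T>A, T>C, T>G); within
#' each class the 16 trinucleotide contexts are ordered by 5' flank then 3'
#' flank, each A,C,G,T — the standard COSMIC ordering, so published catalogs
#' load without re-indexing.
#' @return character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs_channels <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (cl in classes)
    for (f5 in BASES)
      for (f3 in BASES)
        out <- c(out, paste0(f5, "[", cl, "]", f3))
  out
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

#' Map mutations to SBS channel labels
#'
#' @param ref,alt single reference/alternate bases (vectors)
#' @param trinucleotide 3-character contexts, middle base = `ref`
#' @return character vector of channel labels in `sbs_channels()` space
#' @export
sbs_channel_of <- function(ref, alt, trinucleotide) {
  stopifnot(all(substr(trinucleotide, 2, 2) == ref))
  pur <- ref %in% c("A", "G")
  ref2 <- ifelse(pur, chartr("ACGT", "TGCA", ref), ref)
  alt2 <- ifelse(pur, chartr("ACGT", "TGCA", alt), alt)
  ctx2 <- trinucleotide
  ctx2[pur] <- revcomp(trinucleotide[pur])
  paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]", substr(ctx2, 3, 3))
}

#' Build a 96-channel spectrum from a set of mutations
#'
#' @param ref,alt,trinucleotide parallel vectors describing the mutations
#' @return named integer vector of length 96 (canonical channel order);
#'   its sum equals the number of mutations supplied.
#' @export
spectrum_from_mutations <- function(ref, alt, trinucleotide) {
  canon <- sbs_channels()
  ch <- sbs_channel_of(ref, alt, trinucleotide)
  bad <- which(!ch %in% canon)
  if (length(bad)) stop("invalid mutation(s) at position(s): ",
                        paste(bad, collapse = ", "))
  tab <- table(factor(ch, levels = canon))
  stats::setNames(as.integer(tab), canon)
}

# Lawson-Hanson non-negative least squares: min ||A x - b||, x >= 0.
# Small dense problems only (tens of columns); deterministic active-set.
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive) && any(w[!passive] > tol) && iter < 30 * n) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      Q <- P[z[P] <= tol]
      alpha <- min(x[Q] / (x[Q] - z[Q] + 1e-300))
      x <- x + alpha * (z - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

# min ||C a - s||^2  s.t.  a >= 0, sum(a) = 1, via a penalty row enforcing the
# sum constraint (lambda >> data scale) plus a tiny ridge as a deterministic
# minimum-norm tie-break among degenerate minimizers.
simplex_lsq <- function(C, s, lambda = 1e5, ridge = 1e-12) {
  n <- ncol(C)
  A <- rbind(C, rep(lambda, n), diag(sqrt(ridge), n))
  b <- c(s, lambda, numeric(n))
  a <- nnls_fit(A, b)
  if (sum(a) > 0) a / sum(a) else a
}

cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Refit signature activities to a spectrum by constrained least squares
#'
#' Minimizes \eqn{\lVert C a - s \rVert^2} over activities \eqn{a \ge 0},
#' \eqn{\sum a = 1}, where `s` is the observed spectrum normalized to sum 1
#' and `C` the catalog matrix restricted to `signatures`. The solver is a
#' deterministic active-set non-negative least squares with the sum-to-one
#' constraint enforced by a penalty row.
#'
#' @param spectrum 96 non-negative counts (canonical channel order)
#' @param catalog a `signature_catalog`
#' @param signatures subset of catalog signature names (default: all)
#' @return list with `activities` (named, on the simplex), `fit_cosine`
#'   (cosine similarity of reconstruction vs observed spectrum) and `empty`
#'   (TRUE when the spectrum had no mutations; activities all zero).
#' @export
refit_qp <- function(spectrum, catalog, signatures = catalog$signature_names) {
  stopifnot(length(spectrum) == 96, all(spectrum >= 0),
            all(signatures %in% catalog$signature_names))
  C <- catalog$probs[, signatures, drop = FALSE]
  if (sum(spectrum) == 0)
    return(list(activities = stats::setNames(numeric(length(signatures)),
                                             signatures),
                fit_cosine = NA_real_, empty = TRUE))
  s <- spectrum / sum(spectrum)
  a <- simplex_lsq(C, s)
  list(activities = stats::setNames(a, signatures),
       fit_cosine = cosine_sim(as.numeric(C %*% a), s),
       empty = FALSE)
}

#' Backward elimination of spurious signatures
#'
#' Starting from the full fit, repeatedly drops the lowest-activity retained
#' signature and refits; a drop is accepted while the reconstruction cosine
#' stays within `epsilon_cos` of the full-catalog fit. Returns the minimal
#' retained set reached and its refitted activities.
#'
#' @inheritParams refit_qp
#' @param epsilon_cos maximum tolerated loss of fit cosine relative to the
#'   full-signature fit (default 0.01; 0 accepts only drops that leave the
#'   fit unchanged)
#' @return list with `retained` (signature names), `activities` (over the
#'   retained set), `fit_cosine`, and `full_cosine`.
#' @export
filter_spurious <- function(spectrum, catalog,
                            signatures = catalog$signature_names,
                            epsilon_cos = 0.01) {
  full <- refit_qp(spectrum, catalog, signatures)
  if (full$empty)
    return(list(retained = character(0), activities = full$activities,
                fit_cosine = NA_real_, full_cosine = NA_real_))
  retained <- signatures
  fit <- full
  while (length(retained) > 1) {
    drop_sig <- retained[which.min(fit$activities)]
    cand <- setdiff(retained, drop_sig)
    trial <- refit_qp(spectrum, catalog, cand)
    if (full$fit_cosine - trial$fit_cosine < epsilon_cos) {
      retained <- cand
      fit <- trial
    } else break
  }
  list(retained = retained, activities = fit$activities,
       fit_cosine = fit$fit_cosine, full_cosine = full$fit_cosine)
}

#' Fit branch-specific signature activities over a mutational tree
#'
#' For every mutation group (branch of the clone phylogeny carrying
#' mutations) builds its 96-channel spectrum, refits activities, filters
#' spurious signatures, and then harmonizes retained sets across neighboring
#' branches under the assumption that signature gains/losses are rare along
#' a tumor's evolution.
#'
#' Branches with fewer than `min_branch_mutations` mutations do not support
#' branch-specific identification; they inherit the parent branch's retained
#' set (activities refit over it) and are flagged `low_confidence`.
#'
#' @param mtree a `mutation_tree` (see [build_mutation_tree()])
#' @param profile the patient's `mutation_profile`
#' @param catalog a `signature_catalog`
#' @param epsilon_cos see [filter_spurious()]
#' @param isolation_threshold a signature retained on a branch but on neither
#'   its parent nor any child branch is removed when its activity is below
#'   this fraction (default 0.10)
#' @param min_branch_mutations minimum mutations for an independent fit
#'   (default 20)
#' @return a `branch_signatures` object: per-group spectra, activities,
#'   retained sets, fit cosines, flags, and a log of harmonization removals.
#' @export
fit_branch_signatures <- function(mtree, profile, catalog,
                                  epsilon_cos = 0.01,
                                  isolation_threshold = 0.10,
                                  min_branch_mutations = 20) {
  idx <- stats::setNames(seq_along(profile$snv_ids), profile$snv_ids)
  gids <- mtree$groups$id
  spectra <- matrix(0L, length(gids), 96,
                    dimnames = list(gids, sbs_channels()))
  for (g in seq_along(gids)) {
    snvs <- idx[mtree$members[[g]]]
    spectra[g, ] <- spectrum_from_mutations(profile$ref_base[snvs],
                                            profile$alt_base[snvs],
                                            profile$trinucleotide[snvs])
  }
  fits <- vector("list", length(gids))
  flags <- character(length(gids))
  # preorder over groups: parents first (group parent vector; 0 = attached
  # to the germline root)
  ord <- order(mtree$depth)
  for (g in ord) {
    n_mut <- sum(spectra[g, ])
    par <- mtree$group_parent[g]
    if (n_mut < min_branch_mutations && par > 0 &&
        length(fits[[par]]$retained) > 0) {
      sigs <- fits[[par]]$retained
      fit <- refit_qp(spectra[g, ], catalog, sigs)
      fits[[g]] <- list(retained = sigs, activities = fit$activities,
                        fit_cosine = fit$fit_cosine,
                        full_cosine = NA_real_)
      flags[g] <- "low_confidence"
    } else {
      fits[[g]] <- filter_spurious(spectra[g, ], catalog,
                                   epsilon_cos = epsilon_cos)
      flags[g] <- ""
    }
  }
  # harmonization: one preorder sweep; an isolated low-activity signature
  # (absent from parent and all children) is pruned and the branch refit
  removals <- list()
  children <- lapply(seq_along(gids), function(g) which(mtree$group_parent == g))
  for (g in ord) {
    ret <- fits[[g]]$retained
    par <- mtree$group_parent[g]
    neigh <- unique(c(if (par > 0) fits[[par]]$retained,
                      unlist(lapply(children[[g]], function(k) fits[[k]]$retained))))
    iso <- ret[!(ret %in% neigh) & fits[[g]]$activities[ret] < isolation_threshold]
    if (length(iso)) {
      keep <- setdiff(ret, iso)
      if (length(keep) == 0) keep <- ret  # never empty a branch entirely
      if (!identical(keep, ret)) {
        fit <- refit_qp(spectra[g, ], catalog, keep)
        removals[[length(removals) + 1]] <-
          list(group = gids[g], removed = iso)
        fits[[g]]$retained <- keep
        fits[[g]]$activities <- fit$activities
        fits[[g]]$fit_cosine <- fit$fit_cosine
      }
    }
  }
  structure(list(groups = gids, spectra = spectra, fits = fits, flags = flags,
                 removals = removals,
                 signature_names = catalog$signature_names),
            class = "branch_signatures")
}

#' Tabulate branch signature activities
#' @param bs a `branch_signatures` object
#' @return data.frame with columns group, signature, activity, fit_cosine, flag
#' @export
branch_activity_table <- function(bs) {
  rows <- lapply(seq_along(bs$groups), function(g) {
    f <- bs$fits[[g]]
    if (length(f$retained) == 0) return(NULL)
    data.frame(group = bs$groups[g], signature = f$retained,
               activity = as.numeric(f$activities[f$retained]),
               fit_cosine = f$fit_cosine, flag = bs$flags[g],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
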