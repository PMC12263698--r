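# On-disk dialects
#
# Mutation profile: tab-separated, one SNV per row. Fixed leading columns
#   snv_id, ref, alt, trinucleotide   (optional metadata column `chrom:pos`)
# then per-sample count pairs named `<sample>:ref` and `<sample>:alt`.
# Driver list: snv_id <TAB> gene <TAB> label.
# Signature catalog: COSMIC SBS layout, `Type` column like "A[C>A]A" plus one
# numeric column per signature.

BASES <- c("A", "C", "G", "T")

#' Read and validate a mutation profile
#'
#' The mutation profile is the pipeline's sole required input: one row per
#' somatic SNV carrying the reference base, mutant base, trinucleotide context
#' (5'-ref-3') and, for every tumor sample of the patient, a pair of columns
#' `<sample>:ref` / `<sample>:alt` with reference and mutant read counts.
#'
#' @param path path to a tab-separated profile file with a header row.
#' @return a `mutation_profile` object: list with `snv_ids`, `ref_base`,
#'   `alt_base`, `trinucleotide`, `sample_names`, and integer matrices
#'   `ref_count`, `alt_count` (SNVs x samples, sample column order preserved).
#' @details Validation enforces: bases in A/C/G/T with ref != alt; context
#'   middle base equal to the reference base; non-negative counts; every SNV
#'   mutated (alt > 0) in at least one sample; and at least four tumor
#'   samples, the pipeline's hard precondition.
#' @export
read_mutation_profile <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snv_id", "ref", "alt", "trinucleotide")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("mutation profile format error: missing column(s) ",
         paste(miss, collapse = ", "))
  cn <- setdiff(names(tab), c(need, "chrom:pos"))
  refcols <- grep(":ref$", cn, value = TRUE)
  samples <- sub(":ref$", "", refcols)
  altcols <- paste0(samples, ":alt")
  if (length(samples) == 0 || !all(altcols %in% cn))
    stop("mutation profile format error: per-sample columns must come in ",
         "'<sample>:ref'/'<sample>:alt' pairs")
  ref_count <- as.matrix(tab[refcols]); colnames(ref_count) <- samples
  alt_count <- as.matrix(tab[altcols]); colnames(alt_count) <- samples
  prof <- new_mutation_profile(
    snv_ids = as.character(tab$snv_id),
    ref_base = toupper(tab$ref), alt_base = toupper(tab$alt),
    trinucleotide = toupper(tab$trinucleotide),
    ref_count = ref_count, alt_count = alt_count)
  prof
}

new_mutation_profile <- function(snv_ids, ref_base, alt_base, trinucleotide,
                                 ref_count, alt_count) {
  n <- length(snv_ids)
  if (anyDuplicated(snv_ids))
    stop("mutation profile validation error: duplicated snv_id(s): ",
         paste(unique(snv_ids[duplicated(snv_ids)]), collapse = ", "))
  bad <- which(!(ref_base %in% BASES) | !(alt_base %in% BASES) |
                 ref_base == alt_base)
  if (length(bad))
    stop("mutation profile validation error: invalid ref/alt bases for SNV(s): ",
         paste(snv_ids[bad], collapse = ", "))
  bad <- which(nchar(trinucleotide) != 3 |
                 substr(trinucleotide, 2, 2) != ref_base)
  if (length(bad))
    stop("mutation profile validation error: trinucleotide middle base does ",
         "not match ref for SNV(s): ", paste(snv_ids[bad], collapse = ", "))
  storage.mode(ref_count) <- "integer"
  storage.mode(alt_count) <- "integer"
  if (any(is.na(ref_count)) || any(is.na(alt_count)) ||
      any(ref_count < 0) || any(alt_count < 0))
    stop("mutation profile validation error: counts must be non-negative integers")
  never <- which(rowSums(alt_count) == 0)
  if (length(never))
    stop("mutation profile validation error: SNV(s) with no mutant reads in ",
         "any sample: ", paste(snv_ids[never], collapse = ", "))
  samples <- colnames(ref_count)
  if (anyDuplicated(samples)) stop("duplicate sample names")
  if (length(samples) < 4)
    stop("at least four tumor samples required (got ", length(samples), ")")
  rownames(ref_count) <- rownames(alt_count) <- snv_ids
  structure(list(snv_ids = snv_ids, ref_base = ref_base, alt_base = alt_base,
                 trinucleotide = trinucleotide, sample_names = samples,
                 ref_count = ref_count, alt_count = alt_count),
            class = "mutation_profile")
}

#' Write a mutation profile in the package's TSV dialect
#' @param profile a `mutation_profile`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mutation_profile <- function(profile, path) {
  tab <- data.frame(snv_id = profile$snv_ids, ref = profile$ref_base,
                    alt = profile$alt_base,
                    trinucleotide = profile$trinucleotide,
                    check.names = FALSE)
  for (s in profile$sample_names) {
    tab[[paste0(s, ":ref")]] <- profile$ref_count[, s]
    tab[[paste0(s, ":alt")]] <- profile$alt_count[, s]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a driver-mutation list
#'
#' @param path TSV with columns `snv_id`, `gene`, `label` (header optional
#'   when exactly three columns are present).
#' @param profile the patient's `mutation_profile`; every driver snv_id must
#'   occur in it.
#' @return a data.frame with columns snv_id, gene, label.
#' @export
read_driver_list <- function(path, profile) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snv_id", "gene", "label") %in% names(tab))) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) != 3) stop("driver list must have columns snv_id, gene, label")
    names(tab) <- c("snv_id", "gene", "label")
  }
  validate_driver_list(tab, profile)
}

validate_driver_list <- function(tab, profile) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  miss <- setdiff(tab$snv_id, profile$snv_ids)
  if (length(miss))
    stop("driver list validation error: snv_id(s) not in mutation profile: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$label))
    stop("driver list validation error: display labels must be unique")
  tab[c("snv_id", "gene", "label")]
}

#' Read a COSMIC-format SBS signature catalog
#'
#' @param path TSV with a `Type` column of 96 channel labels like `A[C>A]A`
#'   and one numeric column per signature. Rows may be in any order; they are
#'   re-indexed into the canonical channel order.
#' @return a `signature_catalog`: list with `signature_names`,
#'   `channel_order` (the 96 canonical labels) and `probs` (96 x signatures),
#'   columns renormalized to sum exactly 1.
#' @details A column whose sum deviates from 1 by more than 1e-3 is rejected;
#'   smaller drift (rounding in published tables) is renormalized away.
#' @export
read_signature_catalog <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Type" %in% names(tab)) stop("signature catalog must have a 'Type' column")
  new_signature_catalog(as.matrix(tab[setdiff(names(tab), "Type")]),
                        channels = tab$Type)
}

new_signature_catalog <- function(probs, channels = rownames(probs)) {
  canon <- sbs_channels()
  probs <- as.matrix(probs)
  if (nrow(probs) != 96) stop("signature catalog must have 96 channel rows, got ",
                              nrow(probs))
  if (is.null(channels) || !setequal(channels, canon))
    stop("signature catalog channels do not match the 96 canonical SBS channels")
  probs <- probs[match(canon, channels), , drop = FALSE]
  if (any(probs < 0)) stop("signature catalog has negative entries")
  sums <- colSums(probs)
  off <- which(abs(sums - 1) > 1e-3)
  if (length(off))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(probs)[off], collapse = ", "))
  probs <- sweep(probs, 2, sums, "/")
  rownames(probs) <- canon
  structure(list(signature_names = colnames(probs), channel_order = canon,
                 probs = probs),
            class = "signature_catalog")
}

#' Write a signature catalog in COSMIC layout
#' @param catalog a `signature_catalog`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_signature_catalog <- function(catalog, path) {
  tab <- data.frame(Type = catalog$channel_order, catalog$probs,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

file_digest <- function(paths) {
  out <- character(length(paths))
  has_sha <- nzchar(Sys.which("sha256sum"))
  for (i in seq_along(paths)) {
    out[i] <- if (has_sha) {
      paste0("sha256:", strsplit(system2("sha256sum", shQuote(paths[i]),
                                         stdout = TRUE), " ")[[1]][1])
    } else paste0("md5:", unname(tools::md5sum(paths[i])))
  }
  stats::setNames(out, basename(paths))
}

#' Build a reproducibility manifest
#'
#' Records the package version, a timestamp, content digests of the input
#' files, every parameter value used and the random seed, so a run can be
#' reproduced and audited.
#' @param inputs named character vector of input file paths (may be empty)
#' @param params named list of parameter values
#' @param seed integer random seed used for the run
#' @return a `run_manifest` list, serializable to JSON losslessly
#' @export
run_manifest <- function(inputs = character(), params = list(), seed = NA_integer_) {
  structure(list(
    tool = "cloneflow",
    version = as.character(utils::packageVersion("cloneflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_digests = as.list(file_digest(inputs)),
    params = params,
    seed = seed), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`
#' @param path JSON file path to write/read
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}
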