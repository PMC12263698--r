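# End-to-end orchestration: deconvolution -> clone phylogeny -> mutational
# tree + drivers -> branch signatures -> migration graph -> sample tree,
# plus the full on-disk output set and the reproducibility manifest.

default_params <- function() {
  list(presence_threshold = 0.02, max_iter = 10,
       min_alt = 3, err = 0.001, p_cut = 0.01,
       epsilon_cos = 0.01, isolation_threshold = 0.10,
       min_branch_mutations = 20, p_mig = 0.1, origin_cut = 0.3)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numerics where possible. Unknown keys are rejected.
#' @param path config file path
#' @return named list of parameter overrides
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", l)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  unknown <- setdiff(names(out), names(default_params()))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  out
}

#' Run the full tumor-evolution pipeline
#'
#' @param profile a `mutation_profile`
#' @param drivers driver data.frame (snv_id, gene, label) or NULL
#' @param catalog a `signature_catalog`
#' @param sites named character vector: sample name -> anatomical site
#'   (default: each sample its own site)
#' @param params list of parameter overrides (see `cloneflow:::default_params`)
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic step (the pipeline itself is deterministic; the seed guards
#'   future stochastic options and feeds the manifest)
#' @return a `cloneflow_result` list with elements `clones`, `phylogeny`,
#'   `mutation_tree`, `signatures`, `observation_tree`, `locations`,
#'   `migration`, `distances`, `distances_mntd`, `sample_tree`, `params`,
#'   `sites`, `profile`, `drivers`, `catalog`, `seed`.
#' @export
run_pipeline <- function(profile, drivers = NULL, catalog, sites = NULL,
                         params = list(), seed = 1) {
  p <- utils::modifyList(default_params(), params)
  set.seed(seed)
  if (is.null(sites))
    sites <- stats::setNames(profile$sample_names, profile$sample_names)
  if (!is.null(drivers)) drivers <- validate_driver_list(drivers, profile)
  dec <- infer_clones(profile,
                      presence_threshold = p$presence_threshold,
                      max_iter = p$max_iter, min_alt = p$min_alt,
                      err = p$err, p_cut = p$p_cut)
  cp <- dec$phylogeny
  mtree <- build_mutation_tree(cp, drivers)
  bs <- fit_branch_signatures(mtree, profile, catalog,
                              epsilon_cos = p$epsilon_cos,
                              isolation_threshold = p$isolation_threshold,
                              min_branch_mutations = p$min_branch_mutations)
  obs <- expand_tips(cp, dec$clones$f, sites,
                     presence_threshold = p$presence_threshold)
  loc <- infer_locations(obs, p_mig = p$p_mig)
  mg <- build_migration_graph(obs, loc, origin_cut = p$origin_cut)
  D <- sample_distances(cp, dec$clones$f, "unifrac")
  Dm <- sample_distances(cp, dec$clones$f, "mntd",
                         presence_threshold = p$presence_threshold)
  stree <- nj_tree(D)
  structure(list(clones = dec$clones, phylogeny = cp, mutation_tree = mtree,
                 signatures = bs, observation_tree = obs, locations = loc,
                 migration = mg, distances = D, distances_mntd = Dm,
                 sample_tree = stree, params = p, sites = sites,
                 profile = profile, drivers = drivers, catalog = catalog,
                 seed = seed),
            class = "cloneflow_result")
}

mutation_tree_json <- function(mtree) {
  list(groups = lapply(seq_len(nrow(mtree$groups)), function(i) list(
    id = mtree$groups$id[i],
    parent = if (mtree$group_parent[i] == 0) "root"
    else mtree$groups$id[mtree$group_parent[i]],
    count = mtree$groups$count[i],
    clones = mtree$groups$clones[i],
    snv_ids = mtree$members[[i]])),
    drivers = if (is.null(mtree$drivers)) list() else
      lapply(seq_len(nrow(mtree$drivers)), function(j) list(
        snv_id = mtree$drivers$snv_id[j], gene = mtree$drivers$gene[j],
        label = mtree$drivers$label[j],
        group = if (is.na(mtree$drivers$group[j])) "unplaced"
        else mtree$drivers$group[j])))
}

migration_dot <- function(mg) {
  lines <- c("digraph migration {", '  Primary [shape=box];')
  for (o in mg$origin) lines <- c(lines, sprintf("  Primary -> \"%s\";", o))
  if (nrow(mg$edges) > 0) for (k in seq_len(nrow(mg$edges))) {
    e <- mg$edges[k, ]
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="(%s)"%s];', e$from, e$to,
                              e$counts,
                              if (e$low_confidence) ", style=dashed" else ""))
  }
  c(lines, "}")
}

#' Write the complete pipeline output set
#'
#' Emits clone genotypes and frequencies (TSV), the clone phylogeny and
#' sample tree (Newick), the mutational tree (JSON), the migration graph
#' (DOT + JSON), branch signature activities and spectra (TSV), location
#' posteriors (TSV), all figures (SVG), and the reproducibility manifest
#' (JSON). Re-running with identical inputs and seed reproduces every file
#' byte-identically except the manifest timestamp.
#'
#' @param result a `cloneflow_result`
#' @param outdir output directory (created if needed)
#' @param inputs optional named paths of the original input files, digested
#'   into the manifest
#' @return invisible character vector of files written
#' @export
write_outputs <- function(result, outdir, inputs = character()) {
  if (is.null(result$clones) || nrow(result$clones$M) == 0)
    stop("empty clone set: nothing to write")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "figures"), showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  fp <- function(...) file.path(outdir, ...)
  files <- character(0)
  put <- function(path) files <<- c(files, path)
  # tables
  M <- result$clones$M
  utils::write.table(data.frame(clone = rownames(M), M, check.names = FALSE),
                     fp("clones.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  put(fp("clones.tsv"))
  f <- result$clones$f
  utils::write.table(data.frame(sample = rownames(f), round(f, 6),
                                check.names = FALSE),
                     fp("frequencies.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  put(fp("frequencies.tsv"))
  writeLines(rtree_newick(result$phylogeny$tree), fp("clone_tree.nwk"))
  put(fp("clone_tree.nwk"))
  writeLines(ape::write.tree(result$sample_tree), fp("sample_tree.nwk"))
  put(fp("sample_tree.nwk"))
  jsonlite::write_json(mutation_tree_json(result$mutation_tree),
                       fp("mutation_tree.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  put(fp("mutation_tree.json"))
  if (!is.null(result$mutation_tree$drivers)) {
    utils::write.table(result$mutation_tree$drivers, fp("driver_placement.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    put(fp("driver_placement.tsv"))
  }
  writeLines(migration_dot(result$migration), fp("migration_graph.dot"))
  put(fp("migration_graph.dot"))
  jsonlite::write_json(list(origin = result$migration$origin,
                            multimodal_origin = result$migration$multimodal_origin,
                            edges = result$migration$edges),
                       fp("migration_graph.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  put(fp("migration_graph.json"))
  marg <- result$locations$marginals
  utils::write.table(data.frame(node = rownames(marg), round(marg, 6),
                                map = result$locations$map,
                                ambiguous = result$locations$ambiguous,
                                check.names = FALSE),
                     fp("location_posteriors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  put(fp("location_posteriors.tsv"))
  act <- branch_activity_table(result$signatures)
  if (!is.null(act)) {
    act$activity <- round(act$activity, 6)
    act$fit_cosine <- round(act$fit_cosine, 6)
    utils::write.table(act, fp("branch_activities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    put(fp("branch_activities.tsv"))
  }
  sp <- result$signatures$spectra
  utils::write.table(data.frame(group = rownames(sp), sp, check.names = FALSE),
                     fp("branch_spectra.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  put(fp("branch_spectra.tsv"))
  for (metric in c("unifrac", "mntd")) {
    D <- if (metric == "unifrac") result$distances else result$distances_mntd
    utils::write.table(data.frame(sample = rownames(D), round(D, 6),
                                  check.names = FALSE),
                       fp(paste0("sample_distances_", metric, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    put(fp(paste0("sample_distances_", metric, ".tsv")))
  }
  # figures
  figs <- list(
    clone_tree = render_clone_tree_with_frequencies(result$phylogeny,
                                                    result$clones$f),
    mutation_tree = render_mutation_tree(result$mutation_tree),
    signature_layers = render_signature_layers(result$mutation_tree,
                                               result$signatures),
    migration_graph = render_migration_graph(result$migration),
    sample_tree = render_sample_tree(result$sample_tree))
  for (nm in names(figs)) {
    writeLines(figs[[nm]], fp("figures", paste0(nm, ".svg")))
    put(fp("figures", paste0(nm, ".svg")))
  }
  # per-branch spectra with driver channels highlighted
  drv_ch <- NULL
  if (!is.null(result$mutation_tree$drivers)) {
    d <- result$mutation_tree$drivers
    idx <- match(d$snv_id, result$profile$snv_ids)
    drv_ch <- stats::setNames(
      sbs_channel_of(result$profile$ref_base[idx],
                     result$profile$alt_base[idx],
                     result$profile$trinucleotide[idx]), d$label)
  }
  for (i in seq_along(result$signatures$groups)) {
    gidz <- result$signatures$groups[i]
    ch <- NULL
    if (!is.null(drv_ch) && !is.null(result$mutation_tree$drivers)) {
      on_branch <- result$mutation_tree$drivers$group %in% gidz
      if (any(on_branch, na.rm = TRUE)) {
        lab <- result$mutation_tree$drivers$label[which(on_branch)]
        ch <- stats::setNames(lab, unname(drv_ch[lab]))
      }
    }
    svg <- render_spectrum(result$signatures$spectra[i, ],
                           title = gidz, driver_channels = ch)
    writeLines(svg, fp("figures", paste0("spectrum_", gidz, ".svg")))
    put(fp("figures", paste0("spectrum_", gidz, ".svg")))
  }
  man <- run_manifest(inputs = inputs, params = result$params,
                      seed = result$seed)
  write_manifest(man, fp("manifest.json"))
  put(fp("manifest.json"))
  invisible(files)
}

#' Command-line entry point
#'
#' Drives the full pipeline from file paths; used by the `inst/cli` script.
#' @param profile_path,drivers_path,signatures_path input files (drivers may
#'   be NULL); see the package dialects in [read_mutation_profile()] etc.
#' @param outdir output directory
#' @param sites_path optional TSV `sample<TAB>site`; defaults to one site per
#'   sample
#' @param config_path optional flat key=value parameter file
#' @param seed integer seed
#' @return the `cloneflow_result`, invisibly
#' @export
run_cli <- function(profile_path, drivers_path = NULL, signatures_path,
                    outdir, sites_path = NULL, config_path = NULL, seed = 1) {
  profile <- read_mutation_profile(profile_path)
  catalog <- read_signature_catalog(signatures_path)
  drivers <- if (!is.null(drivers_path))
    read_driver_list(drivers_path, profile)
  sites <- NULL
  if (!is.null(sites_path)) {
    st <- utils::read.delim(sites_path, header = FALSE,
                            stringsAsFactors = FALSE)
    sites <- stats::setNames(st[[2]], st[[1]])
  }
  params <- if (!is.null(config_path)) read_config(config_path) else list()
  res <- run_pipeline(profile, drivers, catalog, sites, params, seed)
  inputs <- c(profile = profile_path, signatures = signatures_path)
  if (!is.null(drivers_path)) inputs <- c(inputs, drivers = drivers_path)
  write_outputs(res, outdir, inputs = inputs)
  invisible(res)
}
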