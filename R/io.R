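# Network export (SIF / GraphML), run manifests, and the end-to-end
# pipeline composition.

#' Export a consensus network
#'
#' SIF: one line `u<TAB>sign<TAB>v` per retained pair, oriented along the
#' dominant direction (undirected pairs are written in lexicographic
#' order).  GraphML: all pairs as edges with `freq_uv`, `freq_vu`,
#' `significance` and `sign` attributes.  Both writers are deterministic
#' for identical inputs.
#'
#' @param consensus a [consensus()] result.
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(consensus, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    kept <- consensus[consensus$retained, , drop = FALSE]
    lines <- character(0)
    if (nrow(kept)) {
      u <- ifelse(kept$direction == "reverse", kept$to, kept$from)
      v <- ifelse(kept$direction == "reverse", kept$from, kept$to)
      sgn <- ifelse(is.na(kept$sign), "?", kept$sign)
      lines <- paste(u, sgn, v, sep = "\t")
    }
    writeLines(lines, path)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(freq_uv = "double", freq_vu = "double",
               significance = "double", sign = "string",
               retained = "boolean")
  for (k in names(keys)) {
    xml2::xml_add_child(doc, "key", id = k, `for` = "edge",
                        attr.name = k, attr.type = keys[[k]])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "consensus", edgedefault = "directed")
  for (nd in attr(consensus, "nodes")) {
    xml2::xml_add_child(g, "node", id = nd)
  }
  for (i in seq_len(nrow(consensus))) {
    row <- consensus[i, ]
    e <- xml2::xml_add_child(g, "edge", source = row$from, target = row$to)
    vals <- list(freq_uv = row$freq_fwd, freq_vu = row$freq_rev,
                 significance = row$significance,
                 sign = if (is.na(row$sign)) "?" else row$sign,
                 retained = tolower(as.character(row$retained)))
    for (k in names(vals)) {
      d <- xml2::xml_add_child(e, "data", key = k)
      xml2::xml_text(d) <- as.character(vals[[k]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced the contents of an output directory: the stage
#' name, input file MD5 digests, all parameters (including seeds) and the
#' package version.  Manifests are appended, never overwritten, so a
#' directory accumulates the full history needed to reproduce it.
#'
#' @param dir output directory (created if needed).
#' @param stage stage name.
#' @param inputs named character vector of input file paths (digested).
#' @param params named list of parameters; must include a `seed` entry
#'   for any stochastic stage.
#' @return path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, stage, inputs = character(0), params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entry <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("stmgrn")),
    inputs = as.list(vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))),
    params = params)
  path <- file.path(dir, "manifest.yaml")
  cat(yaml::as.yaml(list(entry)), file = path, append = TRUE)
  invisible(path)
}

#' Read a run manifest
#' @param dir directory holding `manifest.yaml`.
#' @return list of manifest entries.
#' @export
read_manifest <- function(dir) {
  yaml::read_yaml(file.path(dir, "manifest.yaml"))
}

#' Run the full synthetic-to-consensus pipeline
#'
#' Composes the stages end-to-end on synthetic data: (1) generate a
#' timecourse and compendium; (2) per-contrast differential tests;
#' (3) meta-analysis with q-values and DEG selection; (4) discretisation
#' of the compendium; (5) annealing structure search and consensus
#' network.  All stage outputs are written under `out_dir` with one
#' manifest entry per stage; any stage failure aborts with the stage
#' named, and nothing is written until all inputs validate.
#'
#' @param out_dir output directory.
#' @param design a [timecourse_design()] for stage 1.
#' @param bn a [ground_truth_bn()] sampled for the compendium.
#' @param n_compendium number of compendium arrays.
#' @param schedule an [anneal_schedule()] for the structure search.
#' @param threshold consensus retention threshold.
#' @param seed master seed; stage seeds are derived from it.
#' @return list with the main stage results (`meta`, `degs`, `ensemble`,
#'   `consensus`) and `out_dir`.
#' @export
pipeline_run <- function(out_dir,
                         design = default_timecourse_design(),
                         bn = stm_fixture_bn(),
                         n_compendium = 1000L,
                         schedule = NULL,
                         threshold = 0.4,
                         seed = 1L) {
  validate_ground_truth_bn(bn)
  stopifnot(inherits(design, "timecourse_design"))
  if (is.null(schedule)) {
    schedule <- anneal_schedule(budget = 20000, restarts = 5L, seed = seed + 3L)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  tc <- stage("synthesise", {
    design$seed <- seed
    tc <- make_timecourse(design)
    for (ctr in names(tc$arms)) {
      write_matrix(tc$arms[[ctr]]$control, file.path(out_dir, paste0(ctr, "_control.tsv")))
      write_matrix(tc$arms[[ctr]]$treated, file.path(out_dir, paste0(ctr, "_treated.tsv")))
    }
    write.table(tc$truth, file.path(out_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "synthesise", params = list(seed = seed,
      n_genes = design$n_genes, replicates = design$replicates,
      noise_sd = design$noise_sd))
    tc
  })

  pvals <- stage("de_test", {
    tbl <- purrr::imap(tc$arms, function(arm, ctr) {
      de_test(arm$control, arm$treated, contrast = ctr)
    }) |> dplyr::bind_rows()
    write_pvalue_table(tbl, file.path(out_dir, "pvalues.tsv"))
    write_manifest(out_dir, "de_test", params = list(test = "welch"))
    tbl
  })

  meta <- stage("meta_analysis", {
    res <- meta_analyse(pvals)
    write.table(res, file.path(out_dir, "meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, "meta_analysis",
                   inputs = c(pvalues = file.path(out_dir, "pvalues.tsv")),
                   params = list(contrasts = unique(pvals$contrast)))
    res
  })
  degs <- select_degs(pvals)

  disc <- stage("discretise", {
    comp <- sample_compendium(bn, n_compendium, seed = seed + 2L)
    write_matrix(comp$expression, file.path(out_dir, "compendium.tsv"))
    d <- discretise(comp$expression)
    write_matrix(d, file.path(out_dir, "compendium_discrete.tsv"))
    write_manifest(out_dir, "discretise",
                   inputs = c(compendium = file.path(out_dir, "compendium.tsv")),
                   params = list(seed = seed + 2L, n = n_compendium))
    d
  })

  cons <- stage("network_inference", {
    ens <- anneal_search(disc, schedule)
    cn <- consensus(ens, threshold = threshold, data = disc)
    write_network(cn, file.path(out_dir, "consensus.sif"), "sif")
    write_network(cn, file.path(out_dir, "consensus.graphml"), "graphml")
    write_manifest(out_dir, "network_inference",
                   inputs = c(discrete = file.path(out_dir, "compendium_discrete.tsv")),
                   params = list(seed = schedule$seed, budget = schedule$budget,
                                 restarts = schedule$restarts,
                                 threshold = threshold))
    list(ensemble = ens, consensus = cn)
  })

  list(meta = meta, degs = degs, ensemble = cons$ensemble,
       consensus = cons$consensus, truth = tc$truth, out_dir = out_dir)
}
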