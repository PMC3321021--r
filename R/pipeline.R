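# End-to-end orchestration: run the stages of the pipeline in dependency
# order from a single config (YAML/JSON file or list), with fixed seeds, a
# hashed output manifest, and stage-level caching.

stage_defs <- function() {
  list(
    simulate = list(deps = character(0),
                    outputs = c("markers.tsv", "samples.tsv", "truth.json")),
    qc       = list(deps = "simulate", outputs = c("markers_filtered.tsv",
                                                   "qc_report.tsv")),
    dist     = list(deps = "qc", outputs = "nei_li.tsv"),
    tree     = list(deps = "qc", outputs = "nj_tree.nwk"),
    amova    = list(deps = "qc", outputs = "amova.tsv"),
    ibd      = list(deps = c("qc", "amova"), outputs = "ibd.tsv"),
    clusterk = list(deps = "qc", outputs = "delta_k.tsv"),
    popgraph = list(deps = "qc", outputs = c("popgraph_edges.tsv",
                                             "popgraph.graphml")),
    outliers = list(deps = "qc", outputs = "outliers.tsv"))
}

#' Run the pipeline from a single configuration
#'
#' Config keys: `output_dir`, `seed`, `stages` (subset of simulate, qc,
#' dist, tree, amova, ibd, clusterk, popgraph, outliers), plus optional
#' per-stage parameter lists (`simulate`, `qc`, `amova`, `ibd`, `clusterk`,
#' `popgraph`, `outliers`). Alternatively to the simulate stage,
#' `inputs$markers` / `inputs$samples` may point at existing files. Stages
#' run in dependency order; a stage whose outputs all exist is skipped
#' unless an upstream stage was re-run. Every output file is md5-hashed into
#' `manifest.json`; re-running with the same config and seed reproduces the
#' hashes of deterministic stages.
#'
#' @param config list, or path to a YAML or JSON config file
#' @return the manifest (list), invisibly written to
#'   `output_dir/manifest.json`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  out_dir <- config$output_dir %||% stop("config needs output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% stop("config needs a seed")
  stages <- config$stages %||% c("simulate", "qc", "amova")
  defs <- stage_defs()
  unknown <- setdiff(stages, names(defs))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  # close over deps: requested stages plus everything they need
  needed <- stages
  repeat {
    more <- setdiff(unlist(lapply(needed, function(s) defs[[s]]$deps)), needed)
    if ("simulate" %in% more && !is.null(config$inputs)) {
      more <- setdiff(more, "simulate")
    }
    if (!length(more)) break
    needed <- c(needed, more)
  }
  order_all <- intersect(names(defs), needed)
  manifest <- list(seed = seed, stages = list())
  ran <- character(0)
  env <- new.env()
  for (st in order_all) {
    outs <- file.path(out_dir, defs[[st]]$outputs)
    upstream_ran <- length(intersect(defs[[st]]$deps, ran)) > 0
    if (all(file.exists(outs)) && !upstream_ran && !isTRUE(config$force)) {
      status <- "cached"
    } else {
      message("[radiascan] running stage: ", st)
      tryCatch(run_stage(st, config, out_dir, seed, env),
               error = function(e) {
                 stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
                      call. = FALSE)
               })
      ran <- c(ran, st)
      status <- "run"
    }
    miss <- outs[!file.exists(outs)]
    if (length(miss)) {
      stop(sprintf("stage '%s' did not produce expected output file '%s'",
                   st, miss[1]))
    }
    manifest$stages[[st]] <- list(
      status = status,
      outputs = as.list(stats::setNames(unname(tools::md5sum(outs)),
                                        basename(outs))))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

load_markers <- function(config, out_dir, filtered = TRUE) {
  path <- if (filtered) file.path(out_dir, "markers_filtered.tsv")
  else file.path(out_dir, "markers.tsv")
  if (!file.exists(path) && !filtered && !is.null(config$inputs$markers)) {
    path <- config$inputs$markers
  }
  if (!file.exists(path)) stop("missing upstream marker matrix: ", path)
  read_aflp_matrix(path)
}

load_samples <- function(config, out_dir) {
  path <- file.path(out_dir, "samples.tsv")
  if (!file.exists(path) && !is.null(config$inputs$samples)) {
    path <- config$inputs$samples
  }
  if (!file.exists(path)) stop("missing upstream sample table: ", path)
  read_sample_table(path)
}

run_stage <- function(st, config, out_dir, seed, env) {
  switch(st,
    simulate = {
      sp <- do.call(sim_params, c(config$simulate %||% list(),
                                  list(seed = seed)))
      sim <- simulate_metapopulation(sp)
      noisy <- corrupt_and_replicate(sim$markers, e01 = sp$e01, e10 = sp$e10,
                                     replicate_fraction = sp$replicate_fraction,
                                     seed = seed + 1)
      write_aflp_matrix(noisy, file.path(out_dir, "markers.tsv"))
      write_sample_table(sim$samples, file.path(out_dir, "samples.tsv"))
      jsonlite::write_json(
        list(selected = sim$truth$selected, e01 = sp$e01, e10 = sp$e10,
             p_anc = sim$truth$p_anc),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    },
    qc = {
      x <- load_markers(config, out_dir, filtered = FALSE)
      cfg <- do.call(qc_config, config$qc %||% list())
      res <- select_markers(x, assess_repeatability(x), cfg)
      write_aflp_matrix(res$markers, file.path(out_dir, "markers_filtered.tsv"))
      rep <- res$report$per_marker
      rep$retained <- rep$locus_id %in% res$report$retained
      utils::write.table(rep, file.path(out_dir, "qc_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message(sprintf("[radiascan] qc: %d/%d loci retained, error rate %.2f%%",
                      length(res$report$retained), ncol(x),
                      res$report$mean_error_rate))
    },
    dist = {
      x <- load_markers(config, out_dir)
      d <- nei_li_distance(x)
      utils::write.table(as.matrix(d), file.path(out_dir, "nei_li.tsv"),
                         sep = "\t", quote = FALSE)
    },
    tree = {
      x <- load_markers(config, out_dir)
      d <- nei_li_distance(x)
      bt <- config$tree$bootstrap %||% 0
      tr <- neighbor_joining(d, bootstrap = if (bt > 0)
        list(markers = x, n_reps = bt, seed = seed) else NULL)
      write_tree_newick(tr, file.path(out_dir, "nj_tree.nwk"))
    },
    amova = {
      x <- load_markers(config, out_dir)
      st_tab <- load_samples(config, out_dir)
      hier <- hierarchy(st_tab)
      prm <- config$amova %||% list()
      res <- amova(x, hier, n_perm = prm$n_perm %||% 999,
                   seed = seed, min_pop_size = prm$min_pop_size %||% 5)
      tab <- data.frame(source = names(res$sigma), df = res$df[names(res$sigma)],
                        sigma2 = res$sigma, percent = res$percent,
                        phi = NA_real_, p = NA_real_)
      tab$phi[seq_along(res$phi)] <- res$phi
      if (!is.null(res$p)) tab$p[seq_along(res$p)] <- res$p[names(res$phi)]
      utils::write.table(tab, file.path(out_dir, "amova.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    ibd = {
      x <- load_markers(config, out_dir)
      st_tab <- load_samples(config, out_dir)
      hier <- hierarchy(st_tab)
      prm <- config$ibd %||% list()
      fst <- pairwise_fst(x, hier, min_pop_size = prm$min_pop_size %||% 2)
      km <- geodesic_km_matrix(st_tab)
      common <- intersect(rownames(fst), rownames(km))
      mt <- mantel_test(dist_matrix(as.matrix(fst)[common, common], "fst"),
                        dist_matrix(as.matrix(km)[common, common], "km"),
                        n_perm = prm$n_perm %||% 1e4, seed = seed)
      ut <- which(upper.tri(as.matrix(fst)[common, common]), arr.ind = TRUE)
      scatter <- data.frame(pop_a = common[ut[, 1]], pop_b = common[ut[, 2]],
                            fst = as.matrix(fst)[common, common][ut],
                            km = as.matrix(km)[common, common][ut])
      attr(scatter, "mantel") <- mt
      utils::write.table(cbind(scatter, r = mt$r, p = mt$p),
                         file.path(out_dir, "ibd.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    clusterk = {
      x <- load_markers(config, out_dir)
      prm <- config$clusterk %||% list()
      dk <- delta_k_scan(x, k_range = (prm$kmin %||% 1):(prm$kmax %||% 6),
                         n_runs = prm$n_runs %||% 10, seed = seed)
      utils::write.table(dk$table, file.path(out_dir, "delta_k.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    popgraph = {
      x <- load_markers(config, out_dir)
      st_tab <- load_samples(config, out_dir)
      hier <- hierarchy(st_tab)
      prm <- config$popgraph %||% list()
      pg <- build_population_graph(x, hier, alpha = prm$alpha %||% 0.05,
                                   min_pop_size = prm$min_pop_size %||% 3)
      utils::write.table(pg$edges, file.path(out_dir, "popgraph_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_popgraph_graphml(pg, file.path(out_dir, "popgraph.graphml"))
    },
    outliers = {
      x <- load_markers(config, out_dir)
      st_tab <- load_samples(config, out_dir)
      hier <- hierarchy(st_tab)
      prm <- config$outliers %||% list()
      cfg <- fmodel_config(prior_odds = prm$prior_odds %||% 10,
                           n_iter = prm$n_iter %||% 50000,
                           burn_in = prm$burn_in %||% 5000,
                           thin = prm$thin %||% 10, seed = seed)
      motu_of <- stats::setNames(
        tapply(st_tab$group_id, st_tab$population_id, `[`, 1),
        sort(unique(st_tab$population_id)))
      pairs <- prm$pairs %||% default_motu_pairs(motu_of)
      scans <- lapply(pairs, function(pp) fit_fmodel_pair(x, pp, hier, cfg))
      rep <- consistent_outliers(scans, motu_of)
      rows <- do.call(rbind, lapply(names(rep), function(k) {
        data.frame(motu_pair = k, n_pairs = rep[[k]]$n_pairs,
                   avg_n_outliers = rep[[k]]$avg_n_outliers,
                   consistent = paste(rep[[k]]$consistent, collapse = ","),
                   caveat = rep[[k]]$single_population_caveat)
      }))
      utils::write.table(rows, file.path(out_dir, "outliers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    stop("unknown stage: ", st))
}

# all population-pair combinations across every MOTU pair
default_motu_pairs <- function(motu_of) {
  motus <- sort(unique(unname(motu_of)))
  pairs <- list()
  for (i in seq_along(motus)) {
    for (j in seq_along(motus)) {
      if (j <= i) next
      p1 <- names(motu_of)[motu_of == motus[i]]
      p2 <- names(motu_of)[motu_of == motus[j]]
      for (a in p1) for (b in p2) pairs[[length(pairs) + 1]] <- c(a, b)
    }
  }
  pairs
}
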