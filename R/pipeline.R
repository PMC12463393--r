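#' Run the analysis pipeline from a YAML configuration
#'
#' Executes the requested stages in the canonical order
#' `qc -> score -> subtype -> signatures -> prioritize -> screens -> mr`,
#' writing one TSV per result table into the run directory plus a plain
#' text log with package/R versions, seed and parameters. Every output
#' table carries the configuration fingerprint in a `# config_hash:`
#' header comment, and a rerun with the same configuration and seed
#' writes byte-identical tables.
#'
#' The YAML schema: `seed` (required), `outdir`, `stages` (subset of the
#' canonical names), `analysis` (overrides for [analysisConfig()]),
#' and an `input` block - either `simulate: {...}` (fields of
#' [simExpressionConfig()]) or `counts:/genes:/cells:` paths; optional
#' `gene_sets` (GMT path; default: synthetic pathways from the planted
#' truth), `catalog` (subtype TSV; default: the simulated catalog),
#' `pair` (two group labels, default O vs Y), and for the `mr` stage
#' either `mr_exposure`/`mr_outcome` TSV paths or `mr_simulate: {...}`
#' (fields of [gwasSimConfig()]).
#'
#' @param configPath path to the YAML configuration.
#' @return invisibly, the run directory path.
#' @export
runPipeline <- function(configPath) {
  spec <- yaml::read_yaml(configPath)
  if (is.null(spec$seed))
    stop("config must set an integer 'seed' for reproducibility")
  stages <- spec$stages
  canonical <- c("qc", "score", "subtype", "signatures", "prioritize",
                 "screens", "mr")
  if (is.null(stages)) stages <- canonical
  unknown <- setdiff(stages, canonical)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  stages <- canonical[canonical %in% stages]
  outdir <- if (is.null(spec$outdir)) "hypoScreen_run" else spec$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(analysisConfig,
                 c(spec$analysis, list(seed = as.integer(spec$seed))))
  # fingerprint the analysis-relevant configuration (not the output path)
  hash <- .configHash(yaml::as.yaml(spec[setdiff(names(spec), "outdir")]))
  emit <- function(df, name) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  log <- c(paste0("hypoScreen ", as.character(packageVersion("hypoScreen"))),
           R.version.string,
           paste0("seed: ", spec$seed),
           paste0("config_hash: ", hash),
           paste0("stages: ", paste(stages, collapse = ", ")))

  needs_expr <- any(stages != "mr")
  d <- NULL; truth <- NULL; catalog <- NULL; sets <- NULL
  if (needs_expr) {
    if (!is.null(spec$input$simulate)) {
      sim_cfg <- do.call(simExpressionConfig,
                         c(spec$input$simulate,
                           if (is.null(spec$input$simulate$seed))
                             list(seed = as.integer(spec$seed))))
      sim <- simulateExpression(sim_cfg)
      d <- sim$dataset; truth <- sim$truth
      catalog <- simSubtypeCatalog(sim_cfg)
    } else if (!is.null(spec$input$counts)) {
      d <- readCounts(spec$input$counts, spec$input$genes,
                      spec$input$cells)
    } else stop("input block must give either 'simulate' or 'counts'")
    if (!is.null(spec$catalog)) catalog <- readSubtypeCatalog(spec$catalog)
    if (!is.null(spec$gene_sets)) sets <- readGeneSets(spec$gene_sets)
    else if (!is.null(truth))
      sets <- makeSyntheticPathways(truth, seed = cfg$seed)
  }
  pair <- if (is.null(spec$pair)) c("O", "Y") else unlist(spec$pair)

  scores <- NULL; assignment <- NULL
  for (st in stages) {
    log <- c(log, paste0("stage: ", st))
    if (st == "qc") {
      d <- qcFilter(d, cfg)
      ql <- S4Vectors::metadata(d)$qc_log
      emit(data.frame(metric = c("removed_total", "removed_umi",
                                 "removed_mito", "kept"),
                      value = c(ql$n_removed, ql$n_umi, ql$n_mito,
                                ql$n_kept)),
           "qc_summary")
      emit(data.frame(cell_id = colnames(d), group = cellGroups(d),
                      cell_type = cellTypes(d),
                      total_umi = totalUMI(d),
                      mito_pct = round(mitoPercent(d), 6)),
           "qc_cells")
    } else if (st == "score") {
      if (is.null(sets)) stop("score stage needs gene_sets")
      d <- normalizeLog1p(d)
      scores <- scoreCollection(d, sets)
      emit(data.frame(cell_id = rownames(scores),
                      round(scores, 6), check.names = FALSE), "scores")
    } else if (st == "subtype") {
      if (is.null(catalog)) stop("subtype stage needs a catalog")
      assignment <- assignSubtypes(d, catalog)
      wp <- weightedProportions(assignment)
      emit(data.frame(subtype = rownames(wp$proportion),
                      round(wp$proportion, 6), check.names = FALSE),
           "subtype_proportions")
      emit(countRank(assignment, pair[2L], cfg), "subtype_counts")
    } else if (st == "signatures") {
      if (is.null(sets)) stop("signatures stage needs gene_sets")
      neurons <- d[, cellTypes(d) == "Neuron"]
      neurons <- normalizeLog1p(neurons)
      sig <- deriveSignatures(neurons, sets, cfg)
      emit(data.frame(signature = rep(c("c1_up", "c4_up"),
                                      c(length(c1Up(sig)), length(c4Up(sig)))),
                      gene = c(c1Up(sig), c4Up(sig))), "signatures")
      writeGeneSets(sig, file.path(outdir, "signatures.gmt"))
      opp <- tryCatch(validateOpposing(sig, neurons), error = function(e) NULL)
      if (!is.null(opp))
        emit(data.frame(r = opp$r, p = opp$p, pass = opp$pass),
             "signature_opposition")
    } else if (st == "prioritize") {
      if (is.null(assignment)) assignment <- assignSubtypes(d, catalog)
      emit(prioritizeSubtypes(d, assignment, pair, cfg), "prioritization")
    } else if (st == "screens") {
      if (is.null(assignment)) assignment <- assignSubtypes(d, catalog)
      if (is.null(scores)) {
        d <- normalizeLog1p(d)
        scores <- scoreCollection(d, sets)
      }
      ranks <- rankSubtypeScores(assignment, scores, pair[1L], cfg)
      emit(ranks$stats, "rank_stats")
      hits <- intersectionScreen(ranks, cfg)
      emit(hits$top, "screen_top")
      emit(hits$bottom, "screen_bottom")
    } else if (st == "mr") {
      if (!is.null(spec$mr_simulate)) {
        gw_cfg <- do.call(gwasSimConfig,
                          c(spec$mr_simulate,
                            if (is.null(spec$mr_simulate$seed))
                              list(seed = as.integer(spec$seed))))
        gw <- simulateGwasPair(gw_cfg)
        expo <- gw$exposure; outc <- gw$outcome
      } else if (!is.null(spec$mr_exposure)) {
        expo <- readGwas(spec$mr_exposure)
        outc <- readGwas(spec$mr_outcome)
      } else stop("mr stage needs mr_exposure/mr_outcome or mr_simulate")
      res <- mrBidirectional(expo, outc, cfg = cfg)
      rows <- lapply(c("forward", "reverse"), function(dir) {
        f <- res[[dir]]$fits
        if (is.null(f) || !nrow(f)) return(NULL)
        cbind(direction = dir, f)
      })
      emit(do.call(rbind, rows), "mr_results")
      emit(data.frame(
        direction = c("forward", "reverse"),
        pass = c(res$forward$pass, res$reverse$pass),
        reason = c(res$forward$reason, res$reverse$reason),
        ivw_p = c(res$forward$ivw_p, res$reverse$ivw_p),
        heterogeneity = c(res$forward$heterogeneity_flag,
                          res$reverse$heterogeneity_flag),
        pleiotropy = c(res$forward$pleiotropy_flag,
                       res$reverse$pleiotropy_flag),
        class = res$class), "mr_screen")
    }
  }
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
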