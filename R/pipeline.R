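# Integrative delimitation pipeline -----------------------------------------

#' Run the integrative species-delimitation workflow
#'
#' Executes the full pipeline on an alignment: validation and haplotype
#' collapsing, K2P distances, an ABGD prior scan, a strict-clock UPGMA tree
#' (or a user tree), single-threshold GMYC with a likelihood-ratio test
#' against the null, optional conspecificity aggregation over a tree
#' sample, a strict-agreement consensus of the ABGD and GMYC partitions,
#' per-consensus-group diversity and neutrality statistics, hierarchical
#' AMOVA, an optional Mantel isolation-by-distance test, and optional
#' morphological identification. Any stage failure stops the pipeline with
#' a stage-tagged error.
#'
#' @param alignment A [seq_alignment] or path to a FASTA file.
#' @param metadata Optional metadata `data.frame` or CSV path (joined when
#'   `alignment` is a path).
#' @param tree Optional ultrametric `phylo` (default: UPGMA from the
#'   haplotype K2P matrix).
#' @param tree_sample Optional list of trees for conspecificity
#'   aggregation.
#' @param morphology Optional `morpho_table` (labelled rows train the
#'   discriminant; all rows are identified).
#' @param sites Optional `data.frame` `site,lat,lon` for the Mantel test.
#' @param abgd Optional [abgd_config].
#' @param reps Coalescent replicates for neutrality p-values (default
#'   1000).
#' @param permutations Permutations for AMOVA/Mantel (default 999).
#' @param seed Integer seed used for every stochastic stage (default 1).
#' @return Object of class `delim_report`: list with the per-stage results
#'   (`haplotypes`, `distances`, `abgd`, `gmyc`, `lr_test`,
#'   `conspecificity`, `consensus` -- a [partition] over individuals --,
#'   `diversity`, `neutrality`, `amova`, `mantel`, `morphology`), the
#'   echoed `parameters`, and `version`.
#' @export
run_pipeline <- function(alignment, metadata = NULL, tree = NULL,
                         tree_sample = NULL, morphology = NULL, sites = NULL,
                         abgd = abgd_config(), reps = 1000L,
                         permutations = 999L, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  aln <- stage("input", {
    if (is.character(alignment)) read_alignment(alignment, metadata)
    else alignment
  })
  haps <- stage("haplotypes", collapse_haplotypes(aln))
  dm_hap <- stage("distances", distance_matrix(haps$alignment, "K2P"))
  scan <- stage("abgd", abgd_scan(dm_hap, abgd))
  part_abgd <- abgd_best(scan)
  if (is.null(part_abgd))
    part_abgd <- scan$partitions[[1L]]
  tr <- stage("tree", if (is.null(tree)) upgma_clock_tree(dm_hap) else tree)
  fit <- stage("gmyc", gmyc_fit(tr, mode = "single"))
  lr <- stage("gmyc_lr", gmyc_lr_test(fit$logL, fit$null_logL, df = 3L))
  consp <- if (!is.null(tree_sample))
    stage("conspecificity", conspecificity_matrix(tree_sample)) else NULL
  # model selection: the GMYC delimitation enters the consensus only when the
  # threshold model beats the null; otherwise its vote is a single species
  gmyc_part <- if (lr$p.value < 0.05) fit$partition
    else partition(setNames(rep(1L, length(fit$partition$assignment)),
                            names(fit$partition$assignment)), method = "gmyc")
  cons_h <- stage("consensus",
                  consensus_partition(list(part_abgd, gmyc_part)))
  # expand haplotype-level consensus to individuals
  cons <- partition(setNames(cons_h$assignment[haps$membership],
                             names(haps$membership)),
                    method = "consensus", parameters = cons_h$parameters)
  groups <- sort(unique(cons$assignment))
  diversity <- list(); neutrality <- list()
  for (gi in seq_along(groups)) {
    ids <- names(cons$assignment)[cons$assignment == groups[gi]]
    if (length(ids) >= 2L) {
      diversity[[groups[gi]]] <- stage("diversity",
                                       nucleotide_diversity(aln, ids))
      ns <- stage("neutrality", fus_fs(aln, ids))
      if (!ns$undefined)
        ns <- stage("neutrality",
                    neutrality_pvalues(ns, reps = reps, seed = seed + gi))
      neutrality[[groups[gi]]] <- ns
    }
  }
  am <- NULL
  pops <- aln$metadata$population
  if (sum(!is.na(pops)) == length(pops) && length(unique(pops)) >= 2L) {
    dm_ind <- stage("distances", distance_matrix(aln, "K2P"))
    hier <- data.frame(id = aln$ids, population = pops,
                       group = cons$assignment[aln$ids])
    am <- stage("amova", amova(dm_ind, hier, permutations = permutations,
                               seed = seed + 100L))
  }
  mant <- NULL
  if (!is.null(sites) && !is.null(am)) {
    sites_of <- aln$metadata$site
    if (all(!is.na(sites_of)) && all(sites_of %in% sites$site)) {
      geo <- geo_distance_matrix(sites)[sites_of, sites_of]
      dimnames(geo) <- list(aln$ids, aln$ids)
      mant <- stage("mantel", mantel_test(dm_ind, geo,
                                          permutations = permutations,
                                          seed = seed + 200L))
    }
  }
  morph_res <- NULL
  if (!is.null(morphology)) {
    morph_res <- stage("morphology", {
      train <- morphology[morphology$label %in% c("AT", "AZ"), , drop = FALSE]
      model <- hda_fit(train, train$label)
      jk <- hda_jackknife(train, train$label)
      list(model = model, jackknife = jk,
           identification = identify_specimens(morphology, model))
    })
  }
  structure(list(
    haplotypes = haps, distances = dm_hap, abgd = scan,
    abgd_partition = part_abgd, tree = tr, gmyc = fit, lr_test = lr,
    conspecificity = consp, consensus = cons, diversity = diversity,
    neutrality = neutrality, amova = am, mantel = mant,
    morphology = morph_res,
    parameters = list(reps = reps, permutations = permutations, seed = seed,
                      abgd = unclass(abgd)),
    version = as.character(utils::packageVersion("delimkit"))),
    class = "delim_report")
}

#' @export
print.delim_report <- function(x, ...) {
  cat("Integrative delimitation report\n")
  cat("  haplotypes:", length(x$haplotypes$haplotypes), "from",
      length(x$haplotypes$membership), "individuals\n")
  cat("  ABGD:", x$abgd_partition$n_groups, "groups (most stable)\n")
  cat("  GMYC:", x$gmyc$entities, "entities at T =",
      format(x$gmyc$threshold, digits = 4), "; LR chi2 =",
      format(x$lr_test$statistic, digits = 5), ", p =",
      format.pval(x$lr_test$p.value, digits = 3), "\n")
  cat("  consensus:", x$consensus$n_groups, "species",
      if (isTRUE(x$consensus$parameters$disagreement))
        "(methods disagree)" else "(methods agree)", "\n")
  for (g in names(x$neutrality)) {
    ns <- x$neutrality[[g]]
    cat("  ", g, ": pi = ", format(x$diversity[[g]]$pi, digits = 3),
        ", D = ", format(ns$D, digits = 3), ", Fs = ",
        format(ns$Fs, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$amova))
    cat("  AMOVA among-group:", format(x$amova$table$percent[1L], digits = 4),
        "%\n")
  if (!is.null(x$morphology))
    cat("  morphology jackknife accuracy:",
        format(x$morphology$jackknife$accuracy, digits = 3), "\n")
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Writes the consensus and per-method partitions as TSV, the distance
#' matrix, and a JSON summary of all scalar results.
#'
#' @param report A `delim_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wpart <- function(p, f) {
    utils::write.table(data.frame(id = names(p$assignment),
                                  group = p$assignment),
                       file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wpart(report$consensus, "consensus_partition.tsv")
  wpart(report$abgd_partition, "abgd_partition.tsv")
  wpart(report$gmyc$partition, "gmyc_partition.tsv")
  write_distance_matrix(report$distances, file.path(dir, "haplotype_k2p.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summary <- list(
      n_haplotypes = length(report$haplotypes$haplotypes),
      abgd_groups = report$abgd_partition$n_groups,
      gmyc_entities = report$gmyc$entities,
      gmyc_threshold = report$gmyc$threshold,
      gmyc_logL = report$gmyc$logL,
      gmyc_null_logL = report$gmyc$null_logL,
      lr_chi2 = report$lr_test$statistic,
      lr_p = report$lr_test$p.value,
      consensus_groups = report$consensus$n_groups,
      parameters = report$parameters,
      version = report$version)
    jsonlite::write_json(summary, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
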