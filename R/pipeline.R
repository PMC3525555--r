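#' Run the full species-delimitation pipeline
#'
#' Chains the analysis stages on one data bundle: optional haplotype
#' collapsing, GMYC fitting (single then multiple threshold) on the
#' chronogram, genealogical concordance of the resulting putative species
#' against per-locus gene trees, multispecies-coalescent comparison of the
#' 1-species / GMYC-single / GMYC-multiple scenarios, and phenotype-clade
#' association when a character matrix is supplied. Each stage's table is
#' written as TSV (plus a JSON report for the GMYC stage) under `out_dir`;
#' outputs are deterministic given identical inputs, so reruns are
#' byte-identical. Stages whose inputs are missing are skipped with a
#' logged notice; a stage failure is reported with its stage name and
#' earlier outputs are retained.
#'
#' @param chronogram Ultrametric `phylo` (or newick path): the tree the
#'   GMYC stage runs on.
#' @param gene_trees Named list of per-locus `phylo` (or paths); optional.
#' @param combined_tree Optional combined-data `phylo` (or path) scored as
#'   an extra concordance column.
#' @param alignment Optional named character vector of sequences (or FASTA
#'   paths) for haplotype collapsing.
#' @param character_matrix Optional character matrix (data frame or TSV
#'   path with a `specimen` column).
#' @param out_dir Output directory (created if needed).
#' @param support_threshold Bootstrap threshold for concordance (default 70).
#' @param theta,theta_policy Passed to [compare_scenarios()].
#' @param exclude_species,exclude_characters Passed to [phenotype_report()].
#' @param seed Integer seed recorded in the log (the pipeline itself is
#'   deterministic; the seed is for provenance when inputs were simulated).
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(chronogram,
                         gene_trees = NULL,
                         combined_tree = NULL,
                         alignment = NULL,
                         character_matrix = NULL,
                         out_dir,
                         support_threshold = 70,
                         theta = 1,
                         theta_policy = c("fixed", "profile"),
                         exclude_species = character(0),
                         exclude_characters = character(0),
                         seed = 1L) {
  theta_policy <- match.arg(theta_policy)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("coaldelim pipeline run",
                 paste0("package version: ",
                        as.character(utils::packageVersion("coaldelim"))),
                 paste0("seed: ", seed),
                 paste0("support_threshold: ", support_threshold),
                 paste0("theta: ", theta, " (", theta_policy, ")"))
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  results <- list()
  failed <- character(0)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      failed <<- c(failed, name)
      note("stage '", name, "' FAILED: ", conditionMessage(e))
      NULL
    })
  }
  write_tsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("wrote ", file)
  }

  if (is.character(chronogram)) chronogram <- read_newick(chronogram)
  if (!is.null(gene_trees)) {
    gene_trees <- lapply(gene_trees, function(g) {
      if (is.character(g)) read_newick(g, supports = TRUE) else g
    })
  }
  if (is.character(combined_tree)) {
    combined_tree <- read_newick(combined_tree, supports = TRUE)
  }
  if (is.character(character_matrix)) {
    character_matrix <- utils::read.delim(character_matrix,
                                          check.names = FALSE,
                                          colClasses = "character")
  }

  # -- haplotypes ------------------------------------------------------
  if (!is.null(alignment)) {
    results$haplotypes <- stage("collapse", {
      if (is.character(alignment) && all(file.exists(alignment))) {
        alignment <- read_fasta_alignment(alignment)
      }
      col <- collapse_identical_haplotypes(alignment)
      write_tsv(col$groups, "haplotypes.tsv")
      col
    })
  } else {
    note("no alignment given: haplotype stage skipped")
  }

  # -- GMYC ------------------------------------------------------------
  results$gmyc_single <- stage("gmyc-single", fit_single_threshold(chronogram))
  results$gmyc_multiple <- stage("gmyc-multiple", {
    fit_multiple_threshold(chronogram, init = results$gmyc_single)
  })
  if (!is.null(results$gmyc_single)) {
    stage("gmyc-report", {
      fits <- purrr::compact(list(single = results$gmyc_single,
                                  multiple = results$gmyc_multiple))
      rep <- lapply(fits, function(f) {
        list(method = f$method,
             params = as.list(f$params),
             thresholds_time = -f$thresholds,
             logL = f$logL, logL0 = f$null$logL,
             LRT = list(statistic = f$LRT$statistic, df = f$LRT$df,
                        p = f$LRT$p.value),
             n_entities = f$n_entities,
             confidence_entities = f$conf_entities,
             clusters = f$clusters,
             singletons = f$singletons)
      })
      jsonlite::write_json(rep, file.path(out_dir, "gmyc_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note("wrote gmyc_fit.json")
      ent <- dplyr::bind_rows(
        lapply(names(fits), function(nm) {
          dplyr::mutate(tidy(fits[[nm]]), method = nm)
        }))
      write_tsv(ent, "gmyc_entities.tsv")
      write_tsv(as_tibble(ltt_curve(chronogram)), "ltt.tsv")
      NULL
    })
  }

  scenarios <- list()
  all_samples <- chronogram$tip.label
  scenarios[["1-species"]] <- tibble(sample = all_samples, species = "all")
  if (!is.null(results$gmyc_single)) {
    scenarios[[paste0("gmyc-single-", results$gmyc_single$n_entities)]] <-
      scenario_from_gmyc(results$gmyc_single)
  }
  if (!is.null(results$gmyc_multiple) &&
      !is.null(results$gmyc_single) &&
      results$gmyc_multiple$n_entities != results$gmyc_single$n_entities) {
    scenarios[[paste0("gmyc-multiple-", results$gmyc_multiple$n_entities)]] <-
      scenario_from_gmyc(results$gmyc_multiple)
  }

  # -- concordance -----------------------------------------------------
  if (!is.null(gene_trees) && length(scenarios) > 1) {
    results$concordance <- stage("concordance", {
      tabs <- lapply(names(scenarios)[-1], function(nm) {
        ct <- concordance_table(gene_trees, scenarios[[nm]],
                                combined = combined_tree,
                                support_threshold = support_threshold)
        dplyr::mutate(concordance_wide(ct), scenario = nm)
      })
      out <- dplyr::bind_rows(tabs)
      write_tsv(out, "concordance.tsv")
      out
    })
  } else {
    note("no gene trees given: concordance stage skipped")
  }

  # -- scenario comparison ---------------------------------------------
  if (!is.null(gene_trees) && length(scenarios) >= 2) {
    results$scenarios <- stage("scenarios", {
      cmp <- compare_scenarios(gene_trees, scenarios, theta = theta,
                               theta_policy = theta_policy)
      write_tsv(cmp, "scenarios.tsv")
      cmp
    })
  } else {
    note("scenario comparison skipped (needs gene trees and >= 2 scenarios)")
  }

  # -- phenotype -------------------------------------------------------
  if (!is.null(character_matrix) && length(scenarios) > 1) {
    results$phenotype <- stage("phenotype", {
      ref_tree <- combined_tree %||% chronogram
      rep <- phenotype_report(ref_tree, character_matrix,
                              scenarios[[2]],
                              exclude_species = exclude_species,
                              exclude_characters = exclude_characters)
      write_tsv(rep, "phenotype.tsv")
      rep
    })
  } else {
    note("no character matrix given: phenotype stage skipped")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  results$log <- log_lines
  results$failed <- failed
  results$out_dir <- out_dir
  if (length(failed) > 0) {
    warn(paste0("pipeline stages failed: ", paste(failed, collapse = ", ")))
  }
  invisible(results)
}
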