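# End-to-end orchestration of the synthetic analysis: simulate -> screen ->
# dating -> junctions -> origins -> rate -> HWE -> phenome scan, with
# reproducible seeding and TSV report output.

#' Build a pipeline run configuration
#'
#' All stage seeds are derived deterministically from the single top-level
#' seed, so two runs with the same configuration produce byte-identical
#' tables.
#'
#' @param out_dir output directory for report tables.
#' @param seed master integer seed.
#' @param stages stages to run, in order, a subset of
#'   `c("simulate", "screen", "tmrca", "junctions", "origins", "rate",
#'   "hwe", "phewas")`. Later stages require the earlier ones.
#' @param cohort named list of overrides passed to [cohort_spec()] (the
#'   default demonstration cohort is 20,000 males and 20,000 females).
#' @param balance_threshold sex-balance filter threshold.
#' @param G generations to the planted Y-STR founder (dating stage).
#' @param n_str_chromosomes chromosomes simulated for the dating stage.
#' @param n_events planted NAHR origin events (junction stage).
#' @param rate_inputs named list with `S_total`, `s_tip_mean`,
#'   `tmrca_years`, `gen_years` for the rate stage.
#' @param phenotypes named list of overrides passed to [pheno_spec()].
#' @param fdr_level FDR threshold for the phenome scan.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("simulate", "screen", "tmrca", "junctions",
                                       "origins", "rate", "hwe", "phewas"),
                            cohort = list(n_males = 20000, n_females = 20000),
                            balance_threshold = 0.35,
                            G = 65, n_str_chromosomes = 100,
                            n_events = 5,
                            rate_inputs = list(S_total = 60555, s_tip_mean = 1300,
                                               tmrca_years = 190000, gen_years = 31),
                            phenotypes = list(n_quantitative = 5, n_binary = 5,
                                              effect_map = c(Q1 = 0.3, B1 = log(2))),
                            fdr_level = 0.05) {
    cfg <- list(out_dir = out_dir, seed = check_count(seed, "seed"),
                stages = match.arg(stages, several.ok = TRUE),
                cohort = cohort, balance_threshold = balance_threshold,
                G = G, n_str_chromosomes = n_str_chromosomes,
                n_events = n_events, rate_inputs = rate_inputs,
                phenotypes = phenotypes, fdr_level = fdr_level)
    class(cfg) <- "run_config"
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the synthetic analysis pipeline end to end
#'
#' Executes the selected stages on synthetic data with known truth and
#' writes one TSV report per stage plus a `run_metadata.yaml` carrying the
#' configuration hash and all derived seeds. Stage failures abort with an
#' error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stages <- config$stages

  if ("simulate" %in% stages) {
    res$cohort <- run_stage("simulate", {
      spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
      simulate_cohort(spec)
    })
    write_tsv(res$cohort$intensities, config$out_dir, "intensities.tsv")
    write_tsv(res$cohort$markers, config$out_dir, "markers.tsv")
    write_tsv(res$cohort$truth, config$out_dir, "truth.tsv")
  }

  if ("screen" %in% stages) {
    res$screen <- run_stage("screen", {
      co <- res$cohort
      balance <- sex_balance_filter(co$intensities, co$markers,
                                    threshold = config$balance_threshold)
      normalized <- normalize_intensities(co$intensities, co$markers)
      bands <- build_reference_bands(normalized, co$intensities$sex)
      calls <- classify_samples(normalized, bands, co$intensities$sex, balance)
      list(bands = bands, calls = calls, incidence = incidence_summary(calls))
    })
    write_tsv(res$screen$calls, config$out_dir, "dosage_calls.tsv")
    write_tsv(res$screen$incidence, config$out_dir, "incidence.tsv")
  }

  if ("tmrca" %in% stages) {
    res$tmrca <- run_stage("tmrca", {
      gspec <- genealogy_spec(n_chromosomes = config$n_str_chromosomes,
                              G = config$G, seed = config$seed + 1L)
      sim <- simulate_star_strs(gspec)
      est <- asd_tmrca(sim$haplotypes)
      write_tsv(data.frame(sim$haplotypes), config$out_dir, "ystr_haplotypes.tsv")
      est
    })
    write_tsv(data.frame(method = res$tmrca$method,
                         T_generations = res$tmrca$T_generations,
                         T_years = res$tmrca$T_years,
                         SE_years = res$tmrca$SE_years),
              config$out_dir, "tmrca.tsv")
  }

  if ("junctions" %in% stages) {
    res$junctions <- run_stage("junctions", {
      model <- synthetic_ltr6b_model()
      tree <- read_haplogroup_tree(system.file("extdata", "epar_haplogroup_tree.nwk",
                                               package = "eparscan"))
      tips <- tree$phylo$tip.label
      events <- with_seed(config$seed + 2L, {
        valid <- setdiff(seq_len(model$frame_length), unlist(lapply(
          model$length_sites, function(s) seq(s$start + 1L, s$start + nchar(s$alleles[[1]]) - 1L))))
        data.frame(branch = sample(tips, config$n_events),
                   crossover = sample(valid, config$n_events),
                   type_id = sprintf("type%d", seq_len(config$n_events)))
      })
      scenario <- origin_scenario(tree, events,
                                  sampled_tips = setNames(rep(3L, length(tips)), tips))
      sim <- simulate_junction_set(model, scenario)
      registry <- classify_junction_types(sim$sequences)
      intervals <- lapply(sim$sequences, function(s) {
        infer_crossover_interval(map_to_references(s, model), model)
      })
      write_junction_fasta(sim$sequences, file.path(config$out_dir, "junctions.fasta"))
      write_tsv(sim$crossovers, config$out_dir, "crossovers_truth.tsv")
      list(model = model, tree = tree, sim = sim, registry = registry,
           intervals = intervals)
    })
    write_tsv(res$junctions$registry$types[, c("type_id", "n_members")],
              config$out_dir, "junction_types.tsv")
  }

  if ("origins" %in% stages) {
    res$origins <- run_stage("origins", {
      min_origins(res$junctions$sim$origins, res$junctions$tree)
    })
    write_tsv(res$origins$per_type, config$out_dir, "origins.tsv")
  }

  if ("rate" %in% stages) {
    res$rate <- run_stage("rate", {
      do.call(branch_generations_and_rate,
              c(config$rate_inputs, list(n_events = res$origins$n_origins)))
    })
    write_tsv(data.frame(generations = res$rate$generations,
                         rate_per_generation = res$rate$rate_per_generation),
              config$out_dir, "nahr_rate.tsv")
  }

  if ("hwe" %in% stages) {
    res$hwe <- run_stage("hwe", {
      calls <- res$screen$calls
      hwe_x_test(
        n_male_carriers = sum(calls$sex == "M" & calls$call == "DEL_HEMI"),
        n_males = sum(calls$sex == "M" & calls$call != "EXCLUDED_IMBALANCE"),
        n_het_females = sum(calls$sex == "F" & calls$call == "HET_DEL"),
        n_hom_females = sum(calls$sex == "F" & calls$call == "HOM_DEL"),
        n_females = sum(calls$sex == "F" & calls$call != "EXCLUDED_IMBALANCE"))
    })
    write_tsv(data.frame(q_hat = res$hwe$q_hat, chi_square = res$hwe$statistic,
                         df = res$hwe$df, p_value = res$hwe$p.value),
              config$out_dir, "hwe.tsv")
  }

  if ("phewas" %in% stages) {
    res$phewas <- run_stage("phewas", {
      calls <- res$screen$calls
      carrier <- setNames(calls$call == "EPAR", calls$sample_id)
      pspec <- do.call(pheno_spec, c(config$phenotypes, list(seed = config$seed + 3L)))
      pheno <- simulate_phenotypes(carrier, pspec)
      phenome_scan(pheno, carrier, fdr_level = config$fdr_level)
    })
    write_tsv(res$phewas, config$out_dir, "phewas.tsv")
  }

  meta <- list(config_hash = config_hash(config), seed = config$seed,
               stages = stages, timestamp = format(Sys.time(), tz = "UTC"),
               package_version = as.character(utils::packageVersion("eparscan")))
  yaml::write_yaml(meta, file.path(config$out_dir, "run_metadata.yaml"))
  invisible(res)
}
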