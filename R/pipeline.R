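configError <- function(...) {
    stop(structure(class = c("clincmap_config_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

inputError <- function(...) {
    stop(structure(class = c("clincmap_input_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default;
#' user-supplied values are merged over these. Thresholds mirror large-scale
#' practice (drugs with at least 1000 exposed patients, diseases with at
#' least 1000 surveyed subjects); synthetic runs lower them in the config.
#'
#' @return named list.
#' @export
defaultPipelineConfig <- function() {
    list(
        seed = 1L,
        alpha = 0.05,
        lambda = "cv",
        n_folds = 5L,
        min_patients_per_drug = 1000L,
        min_samples_per_disease = 1000L,
        k_grid = c(5L, 10L, 15L, 20L),
        group_size = 80L,
        out_dir = "clincmap_out",
        cluster = list(n_row_clusters = 2L, n_col_clusters = 2L),
        simulate = NULL,
        inputs = list()
    )
}

validatePipelineConfig <- function(cfg) {
    if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
        configError("alpha must be in (0, 1), got ", cfg$alpha)
    if (!identical(cfg$lambda, "cv") &&
        (!is.numeric(cfg$lambda) || cfg$lambda < 0))
        configError("lambda must be 'cv' or a number >= 0")
    if (cfg$min_patients_per_drug < 0 || cfg$min_samples_per_disease < 0)
        configError("minimum-sample thresholds must be >= 0")
    if (is.unsorted(cfg$k_grid, strictly = TRUE))
        configError("k_grid must be strictly ascending")
    if (cfg$group_size < 1)
        configError("group_size must be >= 1")
    invisible(cfg)
}

loadPipelineConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) inputError("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    cfg <- utils::modifyList(defaultPipelineConfig(), config)
    validatePipelineConfig(cfg)
    cfg
}

stageLog <- function(stage, t0) {
    message(sprintf("[clinCMap] %-16s %.2fs", stage,
                    as.numeric(proc.time()[3L]) - t0))
}

#' Run the connectivity-mapping pipeline
#'
#' Orchestrates the end-to-end flow: (optional) synthetic-data simulation,
#' drug effect vectors from the longitudinal arm, disease sign vectors from
#' the survey arm, the drug x disease score matrix with per-disease
#' rankings, gold-standard evaluation (precision at K and fold enrichment),
#' and co-clustering of the score matrix. Every output is a plain text
#' table under `out_dir`, plus a `manifest.json` recording the effective
#' configuration. All randomness flows from the config seed, so a rerun
#' with the same config reproduces every output byte for byte.
#'
#' @param config path to a YAML configuration file or an equivalent named
#'   list; see [defaultPipelineConfig()] for the tunables. Either a
#'   `simulate` block or `inputs` paths (`longitudinal`, `survey`,
#'   `gold_standard`) must be supplied.
#' @param outDir,seed optional overrides of the configured values.
#' @param stages which stages to run (in pipeline order); running them one
#'   at a time composes to the same outputs as one full run.
#' @return invisibly, the list of written file paths.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL,
                        stages = c("simulate", "drug-vectors",
                                   "disease-vectors", "score", "evaluate",
                                   "cluster")) {
    cfg <- loadPipelineConfig(if (is.list(config)) config else config)
    if (!is.null(outDir)) cfg$out_dir <- outDir
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    stages <- match.arg(stages, several.ok = TRUE)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    written <- character()
    t0 <- as.numeric(proc.time()[3L])

    paths <- list(
        longitudinal = cfg$inputs$longitudinal,
        survey = cfg$inputs$survey,
        gold_standard = cfg$inputs$gold_standard)

    if ("simulate" %in% stages && !is.null(cfg$simulate)) {
        sim <- do.call(simulateStudy,
                       c(cfg$simulate, list(seed = cfg$seed)))
        writeLongitudinal(sim$ehr, out("longitudinal.tsv"))
        writeSurvey(sim$survey, out("survey.tsv"))
        writeGoldStandard(sim$gold, out("gold_standard.csv"))
        paths <- list(longitudinal = out("longitudinal.tsv"),
                      survey = out("survey.tsv"),
                      gold_standard = out("gold_standard.csv"))
        written <- c(written, unlist(paths))
        stageLog("simulate", t0)
    } else if (is.null(cfg$simulate)) {
        # stages read previously simulated files from out_dir if inputs
        # are not given explicitly
        for (nm in names(paths))
            if (is.null(paths[[nm]])) {
                cand <- out(c(longitudinal = "longitudinal.tsv",
                              survey = "survey.tsv",
                              gold_standard = "gold_standard.csv")[[nm]])
                if (file.exists(cand)) paths[[nm]] <- cand
            }
    } else {
        paths <- list(longitudinal = out("longitudinal.tsv"),
                      survey = out("survey.tsv"),
                      gold_standard = out("gold_standard.csv"))
    }

    if ("drug-vectors" %in% stages) {
        if (is.null(paths$longitudinal) || !file.exists(paths$longitudinal))
            inputError("longitudinal input not found")
        ehr <- readLongitudinal(paths$longitudinal)
        dv <- buildDrugEffectVectors(
            ehr, alpha = cfg$alpha, lambda = cfg$lambda,
            nFolds = cfg$n_folds,
            minPatientsPerDrug = cfg$min_patients_per_drug,
            seed = cfg$seed)
        writeSignVectors(dv, out("drug_vectors.csv"))
        utils::write.csv(signDetails(dv), out("drug_stats.csv"),
                         row.names = FALSE, quote = FALSE)
        written <- c(written, out("drug_vectors.csv"), out("drug_stats.csv"))
        stageLog("drug-vectors", t0)
    }

    if ("disease-vectors" %in% stages) {
        if (is.null(paths$survey) || !file.exists(paths$survey))
            inputError("survey input not found")
        sv <- readSurvey(paths$survey)
        ds <- buildDiseaseVectors(sv, alpha = cfg$alpha,
                                  minSamples = cfg$min_samples_per_disease)
        writeSignVectors(ds, out("disease_vectors.csv"))
        utils::write.csv(signDetails(ds), out("disease_stats.csv"),
                         row.names = FALSE, quote = FALSE)
        written <- c(written, out("disease_vectors.csv"),
                     out("disease_stats.csv"))
        stageLog("disease-vectors", t0)
    }

    if ("score" %in% stages) {
        dv <- readSignVectors(out("drug_vectors.csv"), "drug")
        ds <- readSignVectors(out("disease_vectors.csv"), "disease")
        if (!is.null(cfg$inputs$drug_aliases) &&
            !is.null(cfg$inputs$disease_aliases)) {
            aA <- readAliasMap(cfg$inputs$drug_aliases)
            aB <- readAliasMap(cfg$inputs$disease_aliases)
            catalog <- harmonizeLabs(aA, aB)
            dv <- mapLabs(dv, aA, catalog)
            ds <- mapLabs(ds, aB, catalog)
        } else {
            catalog <- sort(intersect(labCatalog(dv), labCatalog(ds)))
            if (!length(catalog))
                inputError("no shared labs between the two sources")
            dv <- new("SignVectorSet", kind = "drug", details = data.frame(),
                      entries = signMatrix(dv)[, catalog, drop = FALSE])
            ds <- new("SignVectorSet", kind = "disease", details = data.frame(),
                      entries = signMatrix(ds)[, catalog, drop = FALSE])
        }
        sm <- computeScoreMatrix(dv, ds)
        writeScoreMatrixCSV(sm, out("score_matrix.csv"))
        written <- c(written, out("score_matrix.csv"))
        for (d in colnames(scores(sm))) {
            f <- out(sprintf("ranking_%s.csv", d))
            utils::write.csv(rankDrugs(sm, d), f, row.names = FALSE,
                             quote = FALSE)
            written <- c(written, f)
        }
        stageLog("score", t0)
    }

    if ("evaluate" %in% stages) {
        if (is.null(paths$gold_standard) || !file.exists(paths$gold_standard))
            inputError("gold standard input not found")
        gs <- readGoldStandard(paths$gold_standard)
        sm <- readScoreMatrixCSV(out("score_matrix.csv"))
        prec <- list(); fes <- list()
        for (d in colnames(scores(sm))) {
            gold <- indications(gs)[[d]]
            if (is.null(gold) || !length(gold)) next
            rk <- rankDrugs(sm, d)
            ks <- cfg$k_grid[cfg$k_grid <= nrow(rk)]
            prec[[d]] <- data.frame(
                disease = d, k = ks,
                precision = vapply(ks, function(k)
                    precisionAtK(rk$drug_id, gold, k), numeric(1L)))
            fe <- foldEnrichment(rk$drug_id, gold,
                                 min(cfg$group_size, nrow(rk)))
            fe <- cbind(disease = d, fe)
            fe$slope <- if (nrow(fe) >= 2L) feTrend(fe) else NA_real_
            fes[[d]] <- fe
        }
        utils::write.csv(do.call(rbind, prec), out("precision_at_k.csv"),
                         row.names = FALSE, quote = FALSE)
        utils::write.csv(do.call(rbind, fes), out("fold_enrichment.csv"),
                         row.names = FALSE, quote = FALSE)
        written <- c(written, out("precision_at_k.csv"),
                     out("fold_enrichment.csv"))
        stageLog("evaluate", t0)
    }

    if ("cluster" %in% stages) {
        sm <- readScoreMatrixCSV(out("score_matrix.csv"))
        cl <- biclusterScores(sm,
                              nRowClusters = cfg$cluster$n_row_clusters,
                              nColClusters = cfg$cluster$n_col_clusters,
                              seed = cfg$seed)
        reord <- scores(sm)[cl$rowOrder, cl$colOrder, drop = FALSE]
        utils::write.csv(as.data.frame(reord), out("clustered_scores.csv"),
                         quote = FALSE)
        lab <- data.frame(
            id = c(names(cl$rowLabels), names(cl$colLabels)),
            axis = c(rep("drug", length(cl$rowLabels)),
                     rep("disease", length(cl$colLabels))),
            cluster = c(cl$rowLabels, cl$colLabels))
        utils::write.csv(lab, out("cluster_labels.csv"), row.names = FALSE,
                         quote = FALSE)
        written <- c(written, out("clustered_scores.csv"),
                     out("cluster_labels.csv"))
        stageLog("cluster", t0)
    }

    manifest <- list(package = "clinCMap",
                     version = as.character(utils::packageVersion("clinCMap")),
                     seed = cfg$seed,
                     config = cfg[setdiff(names(cfg), "inputs")],
                     inputs = paths)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    written <- c(written, out("manifest.json"))
    invisible(written)
}
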