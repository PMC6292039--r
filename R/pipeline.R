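.STAGES <- c("simulate", "derive", "scan", "classify", "multienv",
             "varcomp", "report")

#' Build a pipeline run configuration
#'
#' The default configuration runs the whole pipeline on a small
#' simulated study (5 chromosomes x 20 markers, 100 RILs, 4
#' environments x 2 replicates, two traits) that finishes on a desktop
#' in minutes. Every stochastic stage derives its own child seed from
#' the master seed, so disabling one stage does not shift another's
#' randomness. A configuration can also be read from YAML with
#' [readRunConfig()].
#'
#' @param seed master seed.
#' @param outDir output directory (created if missing).
#' @param stages stages to run, a subset of simulate, derive, scan,
#'   classify, multienv, varcomp, report (dependency order enforced).
#' @param nChrom,nMarkers,chromLength simulated map dimensions.
#' @param nRil,selfingGenerations,environments,replicates study sizes.
#' @param traits traits to analyse (must exist in the architecture).
#' @param architecture a [QTLArchitecture-class] or NULL for
#'   [demoArchitecture()].
#' @param step,window,nPerm,alpha,maxCofactors,pEnter single-locus scan
#'   parameters.
#' @param pin,eqtlStep,eqtlNPerm,minDist,radius multi-environment scan
#'   parameters (stepwise entry p, e-QTL grid step, e-QTL permutations,
#'   minimum within-chromosome pair distance, m-QTL coincidence
#'   radius).
#' @return A named list (class "hetqtlRunConfig").
#' @export
makeRunConfig <- function(seed = 1, outDir = tempfile("hetqtl_run_"),
                          stages = .STAGES,
                          nChrom = 5, nMarkers = 100, chromLength = 100,
                          nRil = 100, selfingGenerations = 7,
                          environments = 4, replicates = 2,
                          traits = c("BN", "SY"), architecture = NULL,
                          step = 1, window = 10, nPerm = 200,
                          alpha = 0.05, maxCofactors = 10, pEnter = 0.01,
                          pin = 1e-4, eqtlStep = 10, eqtlNPerm = 100,
                          minDist = 20, radius = 5) {
  cfg <- as.list(environment())
  bad <- setdiff(cfg$stages, .STAGES)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  cfg$stages <- .STAGES[.STAGES %in% cfg$stages]
  class(cfg) <- "hetqtlRunConfig"
  cfg
}

#' @rdname makeRunConfig
#' @param path YAML file with (a subset of) the [makeRunConfig()]
#'   fields.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(makeRunConfig, vals)
}

.need <- function(cfg, stage, file, neededBy) {
  if (!file.exists(file.path(cfg$outDir, file)))
    stop(sprintf("stage '%s' needs output of stage '%s'; enable '%s'",
                 neededBy, stage, stage))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate the study
#' (genotypes, cross design, phenotypes, truth ledger), derive HB/MPH
#' datasets, single-locus scans with permutation thresholds and QTL
#' calling, gene-action classification, multi-environment m-QTL/e-QTL
#' analysis with congruence, variance components and heritability, and
#' report rendering — writing tidy CSVs plus a JSON manifest with a
#' checksum per output file. Re-running with the same configuration
#' and seed reproduces every checksum.
#'
#' @param config a configuration from [makeRunConfig()] /
#'   [readRunConfig()].
#' @return The manifest (named list), invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "hetqtlRunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  warnCount <- integer(0)
  ranStages <- character(0)
  withStage <- function(stage, fun) {
    message(sprintf("[%s] running", stage))
    nw <- 0L
    withCallingHandlers(fun(),
                        warning = function(w) {
                          nw <<- nw + 1L
                          invokeRestart("muffleWarning")
                        })
    warnCount[stage] <<- nw
    ranStages <<- c(ranStages, stage)
  }
  out <- function(f) file.path(config$outDir, f)
  envs <- sprintf("E%d", seq_len(config$environments))
  stages <- config$stages

  if ("simulate" %in% stages) withStage("simulate", function() {
    map <- simulateMap(nChrom = config$nChrom, nMarkers = config$nMarkers,
                       chromLength = config$chromLength)
    cfg <- simConfig(nRil = config$nRil,
                     selfingGenerations = config$selfingGenerations,
                     environments = config$environments,
                     replicates = config$replicates,
                     seed = config$seed)
    arch <- config$architecture
    if (is.null(arch)) arch <- demoArchitecture(map, config$environments)
    rils <- simulateRilGenotypes(map, cfg)
    design <- makeIf2Design(rils, seed = .childSeed(config$seed, "design"))
    bcs <- makeBackcrossDesign(rils)
    design <- CrossDesign(if2Pairs = if2Pairs(design),
                          backcrosses = backcrosses(bcs))
    genos <- list(RIL = rils,
                  IF2 = deduceHybridGenotypes(rils, design, "IF2"),
                  HSBCF1 = deduceHybridGenotypes(rils, design, "HSBCF1"),
                  MARBCF1 = deduceHybridGenotypes(rils, design, "MARBCF1"),
                  P1 = parentalGenotypes(map, "P1"),
                  P2 = parentalGenotypes(map, "P2"))
    for (p in names(genos))
      writeCrossCsv(genos[[p]], out(sprintf("genotypes_%s.csv", p)))
    writeCrossDesignCsv(design, out("cross_design.csv"))
    phenoSeed <- .childSeed(config$seed, "phenotypes")
    for (i in seq_along(genos)) {
      p <- names(genos)[i]
      ph <- simulatePhenotypes(genos[[p]], arch, cfg,
                               seed = phenoSeed + i)
      writePhenotypeCsv(ph, out(sprintf("phenotypes_%s.csv", p)))
    }
    emitTruthLedger(arch, out("truth_ledger.csv"))
  })

  loadGeno <- function(p)
    readCrossCsv(out(sprintf("genotypes_%s.csv", p)), population = p)$geno
  loadPheno <- function(p, kind = "raw", file = NULL) {
    f <- if (is.null(file)) sprintf("phenotypes_%s.csv", p) else file
    readPhenotypeCsv(out(f), kind = kind)
  }

  if ("derive" %in% stages) withStage("derive", function() {
    .need(config, "simulate", "phenotypes_RIL.csv", "derive")
    design <- readCrossDesignCsv(out("cross_design.csv"))
    rilPh <- loadPheno("RIL"); p1 <- loadPheno("P1"); p2 <- loadPheno("P2")
    hb <- computeHB(rilPh, p1, p2)
    writePhenotypeCsv(hb, out("hb_RIL.csv"))
    sums <- list(summarizeHeterosis(hb))
    for (p in c("IF2", "HSBCF1", "MARBCF1")) {
      mph <- computeMPH(loadPheno(p), design, p, rilPh, p1, p2)
      writePhenotypeCsv(mph, out(sprintf("mph_%s.csv", p)))
      s <- summarizeHeterosis(mph)
      s$population <- p
      sums[[length(sums) + 1L]] <- s
    }
    sums[[1]]$population <- "RIL"
    write.csv(do.call(rbind, sums), out("heterosis_summary.csv"),
              row.names = FALSE)
  })

  datasetInputs <- function() {
    list(RIL = list(geno = "RIL", pheno = loadPheno("RIL")),
         IF2 = list(geno = "IF2", pheno = loadPheno("IF2")),
         HSBCF1 = list(geno = "HSBCF1", pheno = loadPheno("HSBCF1")),
         MARBCF1 = list(geno = "MARBCF1", pheno = loadPheno("MARBCF1")),
         IF2MPH = list(geno = "IF2",
                       pheno = loadPheno("IF2", "MPH", "mph_IF2.csv")),
         HSBCF1MPH = list(geno = "HSBCF1",
                          pheno = loadPheno("HSBCF1", "MPH",
                                            "mph_HSBCF1.csv")),
         MARBCF1MPH = list(geno = "MARBCF1",
                           pheno = loadPheno("MARBCF1", "MPH",
                                             "mph_MARBCF1.csv")))
  }

  if ("scan" %in% stages) withStage("scan", function() {
    .need(config, "simulate", "genotypes_RIL.csv", "scan")
    .need(config, "derive", "mph_IF2.csv", "scan")
    ds <- datasetInputs()
    recs <- list()
    thrRows <- list()
    permSeed <- .childSeed(config$seed, "permutations")
    for (i in seq_along(ds)) {
      d <- ds[[i]]
      probs <- genotypeProbabilities(loadGeno(d$geno), step = config$step)
      for (tr in config$traits) for (ev in envs) {
        set.seed(permSeed + 1000L * i + match(ev, envs) +
                   10L * match(tr, config$traits))
        prof <- cimScan(d$pheno, probs, tr, environment = ev,
                        window = config$window,
                        maxCofactors = config$maxCofactors,
                        pEnter = config$pEnter, nPerm = config$nPerm,
                        alpha = config$alpha)
        thrRows[[length(thrRows) + 1L]] <- data.frame(
          dataset = names(ds)[i], trait = tr, environment = ev,
          threshold = scanThreshold(prof), stringsAsFactors = FALSE)
        q <- callQtls(prof)
        if (nrow(q)) recs[[length(recs) + 1L]] <- q
      }
    }
    allRecs <- if (length(recs)) do.call(rbind, recs) else
      callQtls(new("ScanProfile", dataset = "RIL", trait = "SY",
                   environment = "E1",
                   grid = data.frame(chrom = "C01", pos = 0, lod = 0,
                                     a = NA_real_, d = NA_real_,
                                     composite = NA_real_, pve = 0),
                   cofactors = character(0), threshold = 1,
                   nPerm = 0L, step = 1))
    write.csv(allRecs, out("qtl_records.csv"), row.names = FALSE)
    write.csv(mergeQtls(allRecs), out("qtl_merged.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, thrRows), out("qtl_thresholds.csv"),
              row.names = FALSE)
  })

  if ("classify" %in% stages) withStage("classify", function() {
    .need(config, "scan", "qtl_records.csv", "classify")
    recs <- read.csv(out("qtl_records.csv"), stringsAsFactors = FALSE)
    calls <- do.call(rbind, lapply(c("IF2", "HSBCF1", "MARBCF1"),
                                   function(p)
                                     classifyGeneActions(recs, p)))
    write.csv(calls, out("gene_action_calls.csv"), row.names = FALSE)
    if (nrow(calls)) {
      sm <- summarizeClasses(calls,
                             pool = list(BCF1 = c("HSBCF1", "MARBCF1")))
      ## per-trait counts (trait recovered from the locus name grammar)
      calls$trait <- parseQtlName(calls$locus)$trait
      byTrait <- aggregate(locus ~ trait + population + class, calls,
                           length)
      names(byTrait)[names(byTrait) == "locus"] <- "count"
    } else {
      sm <- data.frame(population = character(), class = character(),
                       count = integer(), percent = numeric())
      byTrait <- data.frame(trait = character(), population = character(),
                            class = character(), count = integer())
    }
    write.csv(sm, out("gene_action_summary.csv"), row.names = FALSE)
    write.csv(byTrait, out("gene_action_by_trait.csv"), row.names = FALSE)
  })

  if ("multienv" %in% stages) withStage("multienv", function() {
    .need(config, "simulate", "genotypes_RIL.csv", "multienv")
    .need(config, "derive", "mph_IF2.csv", "multienv")
    ds <- datasetInputs()
    permSeed <- .childSeed(config$seed, "permutations")
    mq <- list(); eq <- list()
    for (i in seq_along(ds)) {
      d <- ds[[i]]
      probs <- genotypeProbabilities(loadGeno(d$geno), step = config$step)
      for (tr in config$traits) {
        m <- mqtlScan(d$pheno, probs, tr, pin = config$pin,
                      nPerm = config$nPerm, alpha = config$alpha,
                      window = config$window,
                      maxCofactors = config$maxCofactors,
                      seed = permSeed + 5000L + 100L * i +
                        match(tr, config$traits))
        if (nrow(m$records)) mq[[length(mq) + 1L]] <- m$records
        e <- eqtlScan(d$pheno, probs, tr, pin = config$pin,
                      step = config$eqtlStep, minDist = config$minDist,
                      nPerm = config$eqtlNPerm, alpha = config$alpha,
                      seed = permSeed + 9000L + 100L * i +
                        match(tr, config$traits))
        if (nrow(e$records)) eq[[length(eq) + 1L]] <- e$records
      }
    }
    mqtls <- if (length(mq)) do.call(rbind, mq) else
      data.frame(name = character(), dataset = character(),
                 trait = character(), chrom = character(),
                 pos = numeric(), lod = numeric(), pvTotal = numeric(),
                 pvA = numeric(), pvAE = numeric())
    eqtls <- if (length(eq)) do.call(rbind, eq) else
      data.frame(name = character(), dataset = character(),
                 trait = character(), chrom1 = character(),
                 pos1 = numeric(), chrom2 = character(),
                 pos2 = numeric(), lod = numeric(), pvAA = numeric(),
                 pvAAE = numeric())
    eqtls <- classifyEpistasisType(eqtls, mqtls, radius = config$radius)
    ## m-QTL record sets differ in their per-environment effect columns
    core <- c("name", "dataset", "trait", "chrom", "pos", "lod",
              "pvTotal", "pvA", "pvAE")
    write.csv(mqtls[, intersect(c(core, setdiff(names(mqtls), core)),
                                names(mqtls))],
              out("mqtl_records.csv"), row.names = FALSE)
    write.csv(eqtls, out("eqtl_records.csv"), row.names = FALSE)
    write.csv(summarizePv(mqtls), out("pv_mqtl_summary.csv"),
              row.names = FALSE)
    write.csv(summarizePv(eqtls), out("pv_eqtl_summary.csv"),
              row.names = FALSE)
    if (file.exists(out("qtl_merged.csv"))) {
      single <- read.csv(out("qtl_merged.csv"), stringsAsFactors = FALSE)
      write.csv(congruence(single, mqtls), out("congruence.csv"),
                row.names = FALSE)
    }
  })

  if ("varcomp" %in% stages) withStage("varcomp", function() {
    .need(config, "simulate", "phenotypes_RIL.csv", "varcomp")
    rows <- list()
    for (p in c("RIL", "IF2", "HSBCF1", "MARBCF1")) {
      ph <- loadPheno(p)
      for (tr in config$traits) {
        vc <- estimateComponents(ph, trait = tr)
        vc$population <- p
        rows[[length(rows) + 1L]] <- vc
      }
    }
    vc <- do.call(rbind, rows)
    vc <- vc[, c("population", "trait", "vG", "vGE", "vE", "e", "r",
                 "H2")]
    write.csv(vc, out("variance_components.csv"), row.names = FALSE)
  })

  if ("report" %in% stages) withStage("report", function() {
    tabs <- renderReports(config$outDir)
    for (nm in names(tabs))
      write.csv(tabs[[nm]], out(sprintf("report_%s.csv", nm)),
                row.names = FALSE)
  })

  files <- sort(list.files(config$outDir, pattern = "\\.csv$"))
  manifest <- list(
    package = "hetqtl",
    seed = config$seed,
    stages = ranStages,
    parameters = config[setdiff(names(config), "architecture")],
    warnings = as.list(warnCount),
    files = lapply(files, function(f)
      list(file = f,
           md5 = unname(tools::md5sum(file.path(config$outDir, f))))))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Render publication-style summary tables
#'
#' Formats the pipeline's CSV outputs into the familiar table layouts —
#' per-trait x environment heterosis summaries, variance components
#' with heritability, per-population gene-action counts with
#' percentages, and e-QTL type / explained-variance blocks — rounding
#' to two decimals. The renderer only reads and formats; every number
#' is traceable to a CSV cell.
#'
#' @param outDir a [runPipeline()] output directory.
#' @return Named list of data.frames (heterosis, varcomp, geneAction,
#'   epistasis — whichever inputs exist).
#' @export
renderReports <- function(outDir) {
  rd <- function(f) {
    p <- file.path(outDir, f)
    if (file.exists(p)) read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  r2 <- function(d) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], round, 2)
    d
  }
  out <- list()
  het <- rd("heterosis_summary.csv")
  if (!is.null(het))
    out$heterosis <- r2(het[, c("population", "trait", "environment",
                                "mean", "min", "max", "topMean")])
  vc <- rd("variance_components.csv")
  if (!is.null(vc)) {
    vc[c("vG", "vGE", "vE")] <- lapply(vc[c("vG", "vGE", "vE")],
                                       signif, 4)
    vc$H2 <- round(vc$H2, 2)
    out$varcomp <- vc
  }
  ga <- rd("gene_action_summary.csv")
  if (!is.null(ga)) out$geneAction <- r2(ga)
  gat <- rd("gene_action_by_trait.csv")
  if (!is.null(gat)) out$geneActionByTrait <- gat
  eq <- rd("pv_eqtl_summary.csv")
  et <- rd("eqtl_records.csv")
  if (!is.null(eq) && !is.null(et)) {
    if (nrow(et)) {
      tt <- aggregate(name ~ dataset + trait + type, et, length)
      wide <- stats::reshape(tt, idvar = c("dataset", "trait"),
                             timevar = "type", direction = "wide")
      names(wide) <- sub("^name\\.", "type", names(wide))
      for (ty in c("typeI", "typeII", "typeIII"))
        if (!ty %in% names(wide)) wide[[ty]] <- 0L
      wide[is.na(wide)] <- 0L
      eqs <- merge(wide, eq, by = c("dataset", "trait"), all = TRUE)
    } else eqs <- eq
    out$epistasis <- r2(eqs)
  }
  out
}
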