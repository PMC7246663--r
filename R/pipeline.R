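# One-call orchestration: ingest or simulate, statistics, network,
# communities, reports, manifest.

.writeReport <- function(df, path, header) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

.demographicsTable <- function(cohort) {
  N <- length(cohort)
  binT <- table(ageBin(ages(cohort)))
  sexT <- table(factor(sexes(cohort), levels = c("male", "female")))
  data.frame(
    variable = c(rep("age", 5), rep("sex", 2)),
    level = c(names(binT), names(sexT)),
    n = c(as.integer(binT), as.integer(sexT)),
    pct = c(pctStr(as.integer(binT), N), pctStr(as.integer(sexT), N)),
    stringsAsFactors = FALSE
  )
}

# Table-2-style: per-disease counts/percentages per stratum of a 2-level
# factor plus the group-comparison p-value; Table-3-style for >2 strata
# (plain chi-squared across the strata).
.stratifiedPrevalence <- function(cohort, strata) {
  overall <- prevalenceTable(cohort)
  if (nrow(overall) == 0) return(data.frame())
  out <- data.frame(code = overall$code, stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(overall), length(strata),
                   dimnames = list(overall$code, names(strata)))
  for (s in names(strata)) {
    pt <- prevalenceTable(strata[[s]])
    counts[pt$code[pt$code %in% rownames(counts)], s] <-
      pt$count[pt$code %in% rownames(counts)]
    out[[paste0(s, "_n")]] <- counts[, s]
    out[[paste0(s, "_pct")]] <- pctStr(counts[, s], length(strata[[s]]))
    out[[paste0(s, "_rank")]] <- rank(-counts[, s], ties.method = "min")
  }
  Ns <- vapply(strata, length, 1L)
  test <- character(nrow(out)); pval <- rep(NA_real_, nrow(out))
  for (i in seq_len(nrow(out))) {
    tab <- rbind(counts[i, ], Ns - counts[i, ])
    res <- tryCatch(groupComparison(tab), error = function(e) NULL)
    if (!is.null(res)) { test[i] <- res$test; pval[i] <- res$p_value }
  }
  out$test <- test
  out$p_value <- ifelse(is.na(pval), "NA", sprintf("%.4g", pval))
  out
}

.countDistTable <- function(cohort) {
  strata <- c(list(all = cohort),
              stratifyCohort(cohort, "sex"),
              stratifyCohort(cohort, "age_bin"))
  do.call(rbind, lapply(names(strata), function(s) {
    d <- comorbidityCountDistribution(strata[[s]], label = s)
    data.frame(stratum = s, k = d$k, n = d$n,
               f = sprintf("%.6f", d$f), stringsAsFactors = FALSE)
  }))
}

#' Run the full comorbidity-network pipeline
#'
#' Ingests records (or generates a synthetic cohort), restricts to the
#' index cohort, and writes to `outDir`: a demographics table, stratified
#' prevalence tables with group-comparison p-values (by sex and by age
#' bin), comorbidity-count distributions per stratum, the pair-statistics
#' table, the thresholded network in GEXF/GraphML/edge-list form, the
#' community partition and module report, and a JSON run manifest recording
#' the configuration, seed and package version. The pipeline is a pure
#' function of its inputs: identical inputs and seed give byte-identical
#' outputs. On a stage failure, files already written are removed and the
#' error names the failing stage.
#'
#' @param outDir output directory (created if needed).
#' @param input path to a records file (used when `config` is NULL).
#' @param layout,sep layout and delimiter of `input` (see [readRecords()]).
#' @param config a [SyntheticConfig-class]; when supplied the cohort is
#'   simulated instead of read, and the simulated records plus ground truth
#'   are written alongside the reports.
#' @param indexCodes index-disease code set; defaults to the config's index
#'   code or `"C220"`.
#' @param codeLevel `"full"` or `"category3"` (see [normalizeCodes()]).
#' @param minPrevalence,rrThreshold network thresholds (see
#'   [buildNetwork()]).
#' @param gamma Louvain resolution parameter.
#' @param seed integer seed controlling simulation and community detection.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory objects: `cohort`,
#'   `prevalence`, `pairStats`, `network`, `partition`, `report`,
#'   `manifest`.
#' @export
runPipeline <- function(outDir, input = NULL, layout = "long", sep = ",",
                        config = NULL, indexCodes = NULL,
                        codeLevel = c("full", "category3"),
                        minPrevalence = 0.01, rrThreshold = 1.0,
                        gamma = 1, seed = 1L, quiet = FALSE) {
  codeLevel <- match.arg(codeLevel)
  stopifnot(minPrevalence >= 0, rrThreshold >= 0, gamma > 0)
  if (is.null(input) && is.null(config))
    stop("either 'input' or 'config' must be supplied", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(f) file.path(outDir, f)
  ver <- as.character(packageVersion("ComorbidNet"))
  hdr <- sprintf("ComorbidNet %s seed=%d", ver, as.integer(seed))

  truth <- NULL
  cohort <- stage("ingest", {
    if (!is.null(config)) {
      say("simulating cohort (N=", config@N, ")")
      gen <- generateCohort(config, seed)
      truth <- gen$moduleOf
      writeRecords(gen$cohort, out("cohort_long.csv"), layout = "long")
      written <- c(written, out("cohort_long.csv"))
      gt <- data.frame(code = names(gen$moduleOf),
                       module = as.integer(gen$moduleOf))
      .writeReport(gt, out("ground_truth.csv"), hdr)
      written <- c(written, out("ground_truth.csv"))
      gen$cohort
    } else {
      say("reading records from ", input)
      readRecords(input, layout = layout, sep = sep)
    }
  })
  if (is.null(indexCodes))
    indexCodes <- if (!is.null(config)) config@indexCode else "C220"
  cohort <- stage("index_filter", {
    co <- normalizeCodes(cohort, codeLevel)
    filterIndexCohort(co, normalizeCodeVector(indexCodes))
  })
  say("index cohort: N=", length(cohort))

  stats <- stage("statistics", {
    prev <- prevalenceTable(cohort)
    prevOut <- data.frame(code = prev$code, count = prev$count,
                          prevalence_pct = pctStr(prev$count, attr(prev, "N")),
                          rank = prev$rank, stringsAsFactors = FALSE)
    .writeReport(.demographicsTable(cohort), out("demographics.csv"), hdr)
    .writeReport(prevOut, out("prevalence_overall.csv"), hdr)
    .writeReport(.stratifiedPrevalence(cohort, stratifyCohort(cohort, "sex")),
                 out("prevalence_by_sex.csv"), hdr)
    .writeReport(.stratifiedPrevalence(cohort,
                                       stratifyCohort(cohort, "age_bin")),
                 out("prevalence_by_age.csv"), hdr)
    .writeReport(.countDistTable(cohort), out("comorbidity_counts.csv"), hdr)
    written <- c(written, out(c("demographics.csv", "prevalence_overall.csv",
                                "prevalence_by_sex.csv",
                                "prevalence_by_age.csv",
                                "comorbidity_counts.csv")))
    pc <- pairCounts(cohort)
    rr <- relativeRisk(pc, prev)
    rrOut <- rr
    for (col in c("observed", "expected", "rr", "rrLow", "rrHigh"))
      rrOut[[col]] <- sprintf("%.6g", rr[[col]])
    .writeReport(rrOut, out("pairs.csv"), hdr)
    written <- c(written, out("pairs.csv"))
    list(prev = prev, rr = rr)
  })

  network <- stage("network", {
    net <- buildNetwork(stats$rr, stats$prev,
                        minPrevalence = minPrevalence,
                        rrThreshold = rrThreshold)
    exportNetwork(net, out("network.gexf"), "gexf")
    exportNetwork(net, out("network.graphml"), "graphml")
    exportNetwork(net, out("edges.csv"), "edgelist")
    written <- c(written, out(c("network.gexf", "network.graphml",
                                "edges.csv", "edges_nodes.csv")))
    say("network: ", nNodes(net), " nodes, ", nEdges(net), " edges")
    net
  })

  partition <- NULL
  report <- NULL
  stage("communities", {
    if (nEdges(network) > 0) {
      partition <- louvain(network, seed = seed, gamma = gamma)
      report <- moduleReport(network, partition)
      pdf_ <- data.frame(code = names(membershipVector(partition)),
                         community = as.integer(membershipVector(partition)))
      .writeReport(pdf_, out("partition.csv"), hdr)
      lines <- c(sprintf("# %s", hdr),
                 sprintf("modularity Q = %.6f (gamma = %g), %d modules",
                         modularityValue(partition), gamma,
                         nCommunities(partition)),
                 unlist(lapply(seq_len(nrow(report)), function(i)
                   sprintf("module %d (%d nodes): %s", report$module[i],
                           report$size[i],
                           paste(report$members[[i]], collapse = ", ")))))
      writeLines(lines, out("modules.txt"))
    } else {
      .writeReport(data.frame(code = character(), community = integer()),
                   out("partition.csv"), hdr)
      writeLines(c(sprintf("# %s", hdr), "no edges: no modules detected"),
                 out("modules.txt"))
    }
    written <- c(written, out(c("partition.csv", "modules.txt")))
  })

  manifest <- stage("manifest", {
    man <- list(
      package = "ComorbidNet", version = ver, seed = as.integer(seed),
      parameters = list(index_codes = as.character(indexCodes),
                        code_level = codeLevel,
                        min_prevalence = minPrevalence,
                        rr_threshold = rrThreshold, gamma = gamma),
      input = if (is.null(config)) list(path = input, layout = layout)
              else list(synthetic = TRUE, N = config@N,
                        n_modules = length(config@modules)),
      cohort_N = length(cohort),
      network = list(nodes = nNodes(network), edges = nEdges(network)),
      modularity = if (!is.null(partition)) modularityValue(partition)
                   else NULL,
      n_modules_detected = if (!is.null(partition)) nCommunities(partition)
                           else 0L,
      outputs = sort(basename(c(written)))
    )
    jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    man
  })
  say("done: ", outDir)
  invisible(list(cohort = cohort, prevalence = stats$prev,
                 pairStats = stats$rr, network = network,
                 partition = partition, report = report,
                 manifest = manifest, truth = truth))
}
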