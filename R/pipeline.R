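## End-to-end orchestration: design -> simulate -> aggregate -> footprint ->
## discover -> cluster, with a YAML/JSON run config and a JSON manifest.

#' Default run configuration
#'
#' A flat config document with one section per stage. Seeds are mandatory in
#' files read by [readRunConfig()]; the default here is for interactive use.
#'
#' @param seed master integer seed.
#' @return nested list, the \code{RunConfig}.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(mutation_rate = 0.1, n_variants = 1500L,
                  barcode_length = 20L, median_barcodes = 13),
    simulate = list(conditions = c("condA", "condB"),
                    active_in = "condA", with_repressor = TRUE,
                    depth_dna = 1e6, depth_rna = 1e6, replicates = 2L),
    footprint = list(pseudocount = 0.5),
    discover = list(kernel_sigma = 3, cv_ratio_threshold = 0.5,
                    activity_threshold = 0.6, posterior_cut = 0.5,
                    merge_gap = 2L, min_length = 4L),
    cluster = list(replicate_floor = 0.3))
}

#' Read and validate a run configuration
#'
#' Accepts YAML or JSON. Validation is a pre-flight check: unknown sections
#' and missing mandatory fields (notably \code{seed}) fail before any compute.
#'
#' @param path config file path.
#' @return validated \code{RunConfig} list (defaults filled in per section).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set an explicit seed")
  base <- defaultRunConfig(cfg$seed)
  known <- names(base)
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config sections: ", paste(extra, collapse = ", "))
  for (sec in setdiff(known, "seed")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(base[[sec]]))
      if (length(bad))
        stop("unknown fields in [", sec, "]: ", paste(bad, collapse = ", "))
      base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    }
  }
  base
}

#' Run the simulation-backed analysis pipeline
#'
#' Chains the stages end to end for a set of promoter regions: design the
#' mutant libraries and barcode maps, simulate DNA/RNA counts from a planted
#' regulatory architecture per promoter, aggregate to variant counts, compute
#' footprints and expression shifts, classify and call sites, and cluster
#' conditions globally. All artifacts are written as TSV/JSON under
#' \code{outDir} together with a manifest recording parameters, seeds and
#' input hashes. Deterministic given the config seed.
#'
#' @param regions list of [PromoterRegion-class] objects (or a single one).
#' @param config a \code{RunConfig} list (see [defaultRunConfig()]).
#' @param outDir output directory, created if needed.
#' @param architectures optional named list of [RegArchitecture-class] per
#'   promoter; default: [exampleArchitecture()] per promoter from the config.
#' @return list with \code{libraries}, \code{barcode_maps}, \code{counts},
#'   \code{footprints}, \code{calls}, \code{classification}, \code{cluster},
#'   \code{manifest} (also written to \code{manifest.json}).
#' @export
runPipeline <- function(regions, config = defaultRunConfig(), outDir,
                        architectures = NULL) {
  if (is(regions, "PromoterRegion")) regions <- list(regions)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- as.integer(config$seed)
  dcfg <- designConfig(mutationRate = config$design$mutation_rate,
                       nVariants = config$design$n_variants,
                       barcodeLength = config$design$barcode_length)
  pool <- designPool(regions, dcfg, seed = seed)
  libs <- pool$libraries
  sim <- config$simulate
  maps <- list(); counts <- list(); fps <- list()
  calls <- list(); classes <- list()
  ccfg <- classifierConfig(config$discover$kernel_sigma,
                           config$discover$cv_ratio_threshold,
                           config$discover$activity_threshold)
  existing <- character()
  for (pi in seq_along(libs)) {
    lib <- libs[[pi]]
    pid <- promoterId(lib)
    per_var <- drawBarcodeMultiplicity(length(lib),
                                       config$design$median_barcodes,
                                       seed = seed + 100L + pi)
    bm <- assignBarcodes(lib, per_var, dcfg, seed = seed + 200L + pi,
                         existing = existing)
    existing <- c(existing, bm$barcode)
    maps[[pid]] <- bm
    arch <- if (!is.null(architectures)) architectures[[pid]]
            else exampleArchitecture(regions[[pi]],
                                     conditions = sim$conditions,
                                     activeIn = sim$active_in,
                                     withRepressor = isTRUE(sim$with_repressor))
    ct <- simulateCounts(lib, bm, arch, conditions = sim$conditions,
                         depthDna = sim$depth_dna, depthRna = sim$depth_rna,
                         replicates = sim$replicates,
                         seed = seed + 300L + pi)
    vc <- aggregateVariantCounts(ct, bm, allVariants = variantIds(lib))
    counts[[pid]] <- vc
    utils::write.table(vc, file.path(outDir, paste0(pid, "_variant_counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cond in sim$conditions) for (r in seq_len(sim$replicates)) {
      fp <- informationFootprint(vc, lib, condition = cond, replicate = r,
                                 pseudocount = config$footprint$pseudocount)
      sh <- expressionShiftMatrix(vc, lib, condition = cond, replicate = r,
                                  pseudocount = config$footprint$pseudocount)
      key <- paste(pid, cond, r, sep = ".")
      fps[[key]] <- fp
      disc <- discoverSites(fp, sh, ccfg,
                            posteriorCut = config$discover$posterior_cut,
                            mergeGap = config$discover$merge_gap,
                            minLength = config$discover$min_length)
      classes[[key]] <- data.frame(promoter_id = pid, condition = cond,
                                   replicate = as.character(r),
                                   class = disc$classification$class,
                                   cv_raw = disc$classification$cv_raw,
                                   cv_ratio = disc$classification$cv_ratio,
                                   stringsAsFactors = FALSE)
      if (nrow(disc$calls)) {
        disc$calls$replicate <- as.character(r)
        calls[[key]] <- disc$calls
      }
      writeFootprint(fp, sh, file.path(outDir, key))
    }
    writePoolFiles(list(manifest = pool$manifest[pool$manifest$promoter_id == pid, ],
                        libraries = libs[pi]), bm,
                   file.path(outDir, paste0(pid, "_design")))
  }
  class_tab <- do.call(rbind, classes); rownames(class_tab) <- NULL
  call_tab <- if (length(calls)) do.call(rbind, calls) else
    data.frame(promoter_id = character(), condition = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  rownames(call_tab) <- NULL
  utils::write.table(class_tab, file.path(outDir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(call_tab, file.path(outDir, "site_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  X <- conditionMatrix(fps)
  clu <- if (nrow(X) >= 2L) clusterGlobal(X) else NULL
  if (!is.null(clu)) writeClusterResult(clu, file.path(outDir, "global"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("regseqtools")),
    seed = seed,
    config = config,
    promoters = vapply(regions, promoterId, character(1)),
    n_variants_per_promoter = vapply(libs, length, integer(1)),
    outputs = list.files(outDir))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(libraries = libs, barcode_maps = maps, counts = counts,
       footprints = fps, calls = call_tab, classification = class_tab,
       cluster = clu, manifest = manifest)
}
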