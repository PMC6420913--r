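#' Default pipeline configuration
#'
#' Nested named list consumed by [runPipeline()]. Keys:
#'
#' * `genome`, `annotations`, `excluded`, `nucleosomes` — input paths
#'   (FASTA, gene TSV, BED, named BED list). Left `NULL` when the `simulate`
#'   stage supplies them.
#' * `scan` — `minArm`, `maxSpacer`, `minTotal` detection thresholds.
#' * `classify` — `atRich`, `tractRich`, `altRich`, `minTract`.
#' * `profile` — `binWidth`, `nControls`, `alphas`, `pool`, `groupBy`
#'   (`"none"`, `"type"` or `"q_group"`), `types` (types profiled when
#'   `groupBy = "type"`), `panels` (list of `c(kind, anchor)` pairs).
#' * `occupancy` — `flank`, `convergentOnly`, `groupBy` (`"none"`,
#'   `"type"`, `"arm_len"` or `"q_group"`), `types`, `armRange`.
#' * `synthetic` — a [synthConfig()].
#' * `seed` — base seed for every stochastic stage.
#'
#' Unknown keys anywhere in the tree are rejected by [runPipeline()].
#'
#' @return the default config list.
#' @export
defaultConfig <- function() {
  list(
    genome = NULL, annotations = NULL, excluded = NULL, nucleosomes = NULL,
    scan = list(minArm = 5L, maxSpacer = 8L, minTotal = 13L),
    classify = list(atRich = 0.6, tractRich = 0.5, altRich = 0.5,
                    minTract = 3L),
    profile = list(binWidth = 10L, nControls = 100L, alphas = c(0.01, 0.001),
                   pool = "per_segment", groupBy = "none",
                   types = c("II", "III", "VII"),
                   panels = list(c("UTR3", "polya_site"),
                                 c("UTR3", "stop_codon"),
                                 c("UTR5", "tss"),
                                 c("ORF", "start_codon"),
                                 c("ORF", "stop_codon"),
                                 c("TAN", "polya_site"),
                                 c("TAN", "tss"),
                                 c("DIV", "tss"),
                                 c("CON", "polya_site"))),
    occupancy = list(flank = 200L, convergentOnly = TRUE, groupBy = "none",
                     types = c("II", "III"), armRange = c(5L, 17L)),
    synthetic = synthConfig(),
    seed = 1L
  )
}

.check_config_keys <- function(config) {
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (section in c("scan", "classify", "profile", "occupancy")) {
    if (is.null(config[[section]])) next
    bad <- setdiff(names(config[[section]]), names(def[[section]]))
    if (length(bad))
      stop("unknown config key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(config)
}

.merge_config <- function(config) {
  def <- defaultConfig()
  if (is.null(config)) return(def)
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_config_keys(config)
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(def[[nm]]) &&
        nm %in% c("scan", "classify", "profile", "occupancy"))
      def[[nm]] <- modifyList(def[[nm]], config[[nm]])
    else def[[nm]] <- config[[nm]]
  }
  def
}

.atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

.stage_paths <- function(outDir) {
  list(sim = file.path(outDir, "sim"),
       irs_tsv = file.path(outDir, "irs.tsv"),
       irs_bed = file.path(outDir, "irs.bed"),
       classified_tsv = file.path(outDir, "irs_classified.tsv"),
       regions_bed = file.path(outDir, "regions.bed"),
       profile_dir = file.path(outDir, "profiles"),
       occupancy_dir = file.path(outDir, "occupancy"),
       manifest = file.path(outDir, "manifest.json"))
}

.resolve_inputs <- function(config, paths) {
  sim <- paths$sim
  genome_path <- config$genome %||% file.path(sim, "genome.fasta")
  annot_path <- config$annotations %||% file.path(sim, "genes.tsv")
  nuc_paths <- config$nucleosomes %||%
    list(mnase = file.path(sim, "nucleosomes_mnase.bed"),
         chemical = file.path(sim, "nucleosomes_chemical.bed"))
  list(genome = genome_path, annotations = annot_path,
       excluded = config$excluded, nucleosomes = nuc_paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_all) else x
}

#' Run the IR analysis pipeline
#'
#' Orchestrates the stages of the analysis and writes stage outputs plus a
#' run manifest under `outDir`. Subcommands:
#'
#' * `simulate` — generate the synthetic genome/annotations/nucleosome data
#'   from `config$synthetic` (seeded with `seed`),
#' * `find-irs` — scan the genome FASTA and write the IR table (TSV + BED),
#' * `classify` — add the seven-type classification to the IR table,
#' * `partition` — write the genic/intergenic region BED,
#' * `profile` — binned positional profiles with randomized controls and
#'   Grubbs calls, one TSV per panel (optionally per type or Q group),
#' * `occupancy` — nNuOc metaprofiles around classified IR centers per
#'   nucleosome condition (optionally grouped by type, arm length or Q
#'   group),
#' * `all` — all of the above in order.
#'
#' Inputs default to the `simulate` stage outputs; supply `config$genome`,
#' `config$annotations` and `config$nucleosomes` to analyze external data.
#' Outputs are written atomically; the manifest (config snapshot, seeds,
#' input checksums, package version, output paths) is written last.
#'
#' @param command one of `"simulate"`, `"find-irs"`, `"classify"`,
#'   `"partition"`, `"profile"`, `"occupancy"`, `"all"`.
#' @param config a config list (see [defaultConfig()]) or the path to a YAML
#'   file holding one; unknown keys are rejected.
#' @param outDir output directory.
#' @param seed base seed; overrides `config$seed`.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(command = c("all", "simulate", "find-irs", "classify",
                                    "partition", "profile", "occupancy"),
                        config = defaultConfig(), outDir = "irscape_out",
                        seed = NULL) {
  command <- match.arg(command)
  config <- .merge_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- .stage_paths(outDir)
  stages <- if (command == "all")
    c("simulate", "find-irs", "classify", "partition", "profile", "occupancy")
  else command
  # on external inputs, `all` skips simulation
  if (command == "all" && !is.null(config$genome))
    stages <- setdiff(stages, "simulate")

  outputs <- list()
  for (stage in stages)
    outputs <- c(outputs, .run_stage(stage, config, paths))

  inputs <- .resolve_inputs(config, paths)
  checksums <- tryCatch(
    as.list(tools::md5sum(unlist(inputs[c("genome", "annotations")]))),
    error = function(e) list())
  manifest <- list(package = "irscape",
                   version = as.character(packageVersion("irscape")),
                   command = command, seed = config$seed,
                   config = .unclass_all(config),
                   input_checksums = checksums,
                   outputs = unlist(outputs, use.names = FALSE))
  .atomic_write(function(p) jsonlite::write_json(manifest, p,
                                                 auto_unbox = TRUE,
                                                 null = "null", digits = NA),
                paths$manifest)
  invisible(manifest)
}

.run_stage <- function(stage, config, paths) {
  inputs <- .resolve_inputs(config, paths)
  need <- function(path, what) {
    if (!all(file.exists(unlist(path))))
      stop("missing input for stage '", stage, "': ", what, " (",
           paste(unlist(path), collapse = ", "),
           "); run the producing stage first or point the config at it")
  }
  load_genome <- function() {
    need(inputs$genome, "genome FASTA")
    readDNAStringSet(inputs$genome)
  }
  load_genes <- function() {
    need(inputs$annotations, "annotation table")
    readGeneModels(inputs$annotations)
  }
  load_excluded <- function() {
    if (is.null(inputs$excluded)) GRanges()
    else rtracklayer::import(inputs$excluded, format = "BED")
  }
  shorten <- function(g) {
    names(g) <- sub(" .*", "", names(g))
    g
  }

  switch(stage,
    "simulate" = {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      sg <- generateSyntheticGenome(do.call(synthConfig, unclass(cfg)))
      writeSyntheticData(sg, paths$sim)
      list(simulate = paths$sim)
    },
    "find-irs" = {
      genome <- shorten(load_genome())
      irs <- do.call(findMaximalIRs, c(list(genome), config$scan))
      .atomic_write(function(p) writeIRs(irs, p, "tsv"), paths$irs_tsv)
      .atomic_write(function(p) writeIRs(irs, p, "bed"), paths$irs_bed)
      list(irs_tsv = paths$irs_tsv, irs_bed = paths$irs_bed)
    },
    "classify" = {
      need(paths$irs_tsv, "IR table")
      irs <- readIRs(paths$irs_tsv)
      irs <- do.call(classifyIRs, c(list(irs), config$classify))
      .atomic_write(function(p) writeIRs(irs, p, "tsv"),
                    paths$classified_tsv)
      list(classified_tsv = paths$classified_tsv)
    },
    "partition" = {
      genome <- shorten(load_genome())
      genes <- load_genes()
      regions <- partitionGenome(genes, excluded = load_excluded(),
                                 seqlengths = setNames(width(genome),
                                                       names(genome)))
      .atomic_write(function(p) {
        gr <- granges(regions)
        mcols(gr)$name <- paste0(regionKind(regions), ":",
                                 mcols(regions)$geneId)
        rtracklayer::export(gr, p, format = "BED")
      }, paths$regions_bed)
      list(regions_bed = paths$regions_bed)
    },
    "profile" = .stage_profile(config, paths, inputs),
    "occupancy" = .stage_occupancy(config, paths, inputs),
    stop("unknown stage: ", stage)
  )
}

.stage_profile <- function(config, paths, inputs) {
  if (!all(file.exists(unlist(inputs[c("genome", "annotations")]))))
    stop("missing input for stage 'profile': genome/annotations; ",
         "run 'simulate' first or point the config at external files")
  genome <- readDNAStringSet(inputs$genome)
  names(genome) <- sub(" .*", "", names(genome))
  genes <- readGeneModels(inputs$annotations)
  excluded <- if (is.null(inputs$excluded)) GRanges()
              else rtracklayer::import(inputs$excluded, format = "BED")
  sl <- setNames(width(genome), names(genome))
  regions <- partitionGenome(genes, excluded = excluded, seqlengths = sl)
  pc <- config$profile
  dir.create(paths$profile_dir, showWarnings = FALSE, recursive = TRUE)

  # expand the configured panels (type- or Q-group-wise where requested)
  panels <- list()
  for (panel in pc$panels) {
    kind <- panel[1]; anchor <- panel[2]
    if (identical(pc$groupBy, "type") && kind %in% c("UTR3", "ORF")) {
      for (tp in pc$types)
        panels[[paste0(kind, "_", anchor, "_type", tp)]] <-
          list(kind = kind, anchorKind = anchor, irType = tp)
    } else if (identical(pc$groupBy, "q_group") && kind == "UTR3") {
      u3 <- regions[as.character(regionKind(regions)) == "UTR3"]
      lg <- lengthGroups(u3, k = 5L)
      for (qi in names(lg$groups)) {
        sub <- u3[lg$groups[[qi]]]
        m10 <- max(pc$binWidth,
                   (min(width(sub)) %/% pc$binWidth) * pc$binWidth)
        span <- if (anchor == "polya_site") c(-(m10 - 1L), 0L)
                else c(1L, m10)
        panels[[paste0(kind, "_", anchor, "_", qi)]] <-
          list(kind = kind, anchorKind = anchor, regions = sub,
               retain = "all", span = span)
      }
    } else {
      panels[[paste0(kind, "_", anchor)]] <-
        list(kind = kind, anchorKind = anchor)
    }
  }

  profs <- profilePanelsWithControls(
    genome, genes, panels, regions = regions, excluded = excluded,
    binWidth = pc$binWidth, nControls = pc$nControls, seed = config$seed,
    alphas = pc$alphas, scanArgs = config$scan,
    classifyArgs = config$classify, pool = pc$pool)

  out <- character()
  for (nm in names(profs)) {
    path <- file.path(paths$profile_dir, paste0(nm, ".tsv"))
    .atomic_write(function(p) writeProfile(profs[[nm]], p), path)
    out <- c(out, path)
  }
  list(profiles = out)
}

.stage_occupancy <- function(config, paths, inputs) {
  if (!file.exists(paths$classified_tsv))
    stop("missing input for stage 'occupancy': classified IR table; ",
         "run 'find-irs' and 'classify' first")
  if (!all(file.exists(unlist(inputs$nucleosomes))))
    stop("missing input for stage 'occupancy': nucleosome BED file(s)")
  genome <- readDNAStringSet(inputs$genome)
  names(genome) <- sub(" .*", "", names(genome))
  sl <- setNames(width(genome), names(genome))
  genes <- readGeneModels(inputs$annotations)
  regions <- partitionGenome(genes, seqlengths = sl)
  irs <- readIRs(paths$classified_tsv, seqlengths = sl)
  oc <- config$occupancy
  dir.create(paths$occupancy_dir, showWarnings = FALSE, recursive = TRUE)

  # IRs inside 3'-UTRs of (optionally convergent-only) genes, with the
  # owning gene's strand attached
  u3 <- regions[as.character(regionKind(regions)) == "UTR3"]
  if (isTRUE(oc$convergentOnly)) {
    keep <- mcols(u3)$geneId %in% convergentGenes(regions)
    u3 <- u3[keep]
  }
  hits <- findOverlaps(GRanges(seqnames(irs), IRanges(irCenter(irs),
                                                      width = 1L)),
                       u3, ignore.strand = TRUE)
  sel <- irs[queryHits(hits)]
  mcols(sel)$geneStrand <-
    genes[mcols(u3)$geneId[subjectHits(hits)], "strand"]
  mcols(sel)$utr3Width <- width(u3)[subjectHits(hits)]

  groups <- switch(oc$groupBy %||% "none",
    "none" = list(all = seq_along(sel)),
    "type" = setNames(lapply(oc$types, function(tp)
      which(as.character(irType(sel)) == tp)), paste0("type", oc$types)),
    "arm_len" = {
      rs <- seq.int(oc$armRange[1], oc$armRange[2])
      setNames(lapply(rs, function(r) which(armLength(sel) == r)),
               paste0("R", rs))
    },
    "q_group" = {
      u3all <- regions[as.character(regionKind(regions)) == "UTR3"]
      lg <- lengthGroups(u3all, k = 5L)
      setNames(lapply(seq_len(nrow(lg$bounds)), function(i)
        which(mcols(sel)$utr3Width >= lg$bounds$min[i] &
                mcols(sel)$utr3Width <= lg$bounds$max[i])),
        lg$bounds$name)
    },
    stop("unknown occupancy groupBy"))

  out <- character()
  for (cond in names(inputs$nucleosomes)) {
    calls <- readNucleosomeCalls(inputs$nucleosomes[[cond]], seqlengths = sl)
    tracks <- occupancyTracks(calls, sl)
    for (gname in names(groups)) {
      idx <- groups[[gname]]
      if (length(idx) == 0L) next
      prof <- nnuocProfile(tracks, sel[idx], flank = oc$flank,
                           condition = cond)
      path <- file.path(paths$occupancy_dir,
                        paste0("nnuoc_", cond, "_", gname, ".tsv"))
      .atomic_write(function(p) writeNnuocProfile(prof, p), path)
      out <- c(out, path)
    }
  }
  list(occupancy = out)
}
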