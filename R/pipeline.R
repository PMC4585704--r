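# End-to-end orchestration: segment -> classify -> HOR -> SF -> insertion
# (-> consensus, tree), with per-array artifacts and a JSON report.

#' Detect the HOR structure of a segmented array
#'
#' Convenience wrapper building the periodicity profile and calling the
#' HOR; arrays with fewer than 4 usable monomers are called monomeric with
#' a warning.
#'
#' @param monomers monomer table or character vector of monomer sequences.
#' @param params [hor_params()].
#' @param align [align_params()].
#' @return An `hor_call`; the profile is attached as attribute
#'   `"profile"`.
#' @export
detect_hor <- function(monomers, params = hor_params(),
                       align = align_params()) {
  seqs <- if (is.data.frame(monomers)) monomers$sequence[!monomers$partial]
          else as.character(monomers)
  if (length(seqs) < 4) {
    warning("fewer than 4 monomers; cannot assess periodicity, ",
            "calling monomeric")
    return(structure(list(period = NA_integer_, label = "monomeric",
                          d_at_period = NA_real_, n_units = NA_integer_),
                     class = "hor_call"))
  }
  prof <- periodicity_profile(seqs, align)
  structure(call_hor(prof, params), profile = prof, class = "hor_call")
}

#' Default pipeline configuration
#'
#' @param ref segmentation reference consensus name.
#' @param segmentation [segmentation_params()].
#' @param hor [hor_params()].
#' @param align [align_params()].
#' @param majority,require_order see [assign_array_sf()].
#' @param long_min_len see [detect_long_monomers()].
#' @param build_consensuses build a per-family consensus from all monomers
#'   of arrays assigned to that family.
#' @param tree build an NJ tree of all non-partial monomers (leaf-capped).
#' @param max_tree_leaves leaf cap for the tree stage (default 500; NJ is
#'   cubic).
#' @param seed RNG seed recorded in the report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ref = "GGO_consensus",
                            segmentation = segmentation_params(),
                            hor = hor_params(), align = align_params(),
                            majority = 0.8, require_order = FALSE,
                            long_min_len = 180,
                            build_consensuses = TRUE, tree = FALSE,
                            max_tree_leaves = 500, seed = 1) {
  structure(list(ref = ref, segmentation = segmentation, hor = hor,
                 align = align, majority = majority,
                 require_order = require_order,
                 long_min_len = long_min_len,
                 build_consensuses = build_consensuses, tree = tree,
                 max_tree_leaves = max_tree_leaves, seed = seed),
            class = "pipeline_config")
}

#' Run the full alphoid analysis pipeline
#'
#' For every array: orientation normalization, monomer segmentation, PRD
#' scanning and A/B classification, HOR calling, SF assignment and
#' extra-long-monomer characterization. Per-array artifacts (monomer BED,
#' classification TSV) and a machine-readable JSON report are written to
#' `out_dir`; per-family consensus FASTA and an optional NJ tree of all
#' monomers are written globally.
#'
#' @param input path to a FASTA file, or a list of `sat_array` objects.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing artifacts.
#' @param config a [pipeline_config()].
#' @return The report: a list with one entry per array (`id`, `n_monomers`,
#'   `orientation`, `hor`, `sf`, `ab_counts`, `insertions`) plus
#'   `families` and `config` summaries. Invisibly also written as
#'   `report.json`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         config = pipeline_config()) {
  arrays <- if (is.character(input) && length(input) == 1)
    read_fasta(input) else input
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  set.seed(config$seed)
  cset <- gorilla_consensuses()

  per_array <- list()
  all_monomers <- list()
  fam_monomers <- list()
  for (arr in arrays) {
    res <- tryCatch(
      .pipeline_one(arr, config, cset, out_dir),
      error = function(e) {
        warning("array '", arr$id, "' failed: ", conditionMessage(e))
        list(id = arr$id, error = conditionMessage(e))
      })
    per_array[[arr$id]] <- res$report
    if (!is.null(res$monomers)) {
      all_monomers[[arr$id]] <- res$monomers
      sf <- res$report$sf$family
      if (!is.null(sf) && sf %in% c("SF1", "SF2", "SF3", "monomeric"))
        fam_monomers[[sf]] <- c(fam_monomers[[sf]],
                                res$monomers$sequence[!res$monomers$partial])
    }
  }

  families <- list()
  if (config$build_consensuses) {
    for (fam in names(fam_monomers)) {
      seqs <- fam_monomers[[fam]]
      if (length(seqs) < 2) next
      cons <- build_consensus(align_monomers(seqs, config$ref, config$align),
                              name = paste0(fam, "_consensus"))
      families[[fam]] <- list(n_monomers = length(seqs),
                              consensus = cons$sequence)
      if (!is.null(out_dir))
        write_fasta(stats::setNames(cons$sequence, cons$name),
                    file.path(out_dir, paste0(fam, "_consensus.fasta")))
    }
  }

  if (config$tree && length(all_monomers)) {
    seqs <- unlist(lapply(all_monomers, function(m) {
      stats::setNames(m$sequence[!m$partial],
                      paste0(m$array_id[!m$partial], "_",
                             m$index[!m$partial]))
    }))
    if (length(seqs) > config$max_tree_leaves)
      seqs <- seqs[seq_len(config$max_tree_leaves)]
    if (length(seqs) >= 3) {
      tr <- nj_tree(monomer_distance_matrix(seqs, config$align))
      if (!is.null(out_dir))
        ape::write.tree(tr, file.path(out_dir, "monomers.nwk"))
    }
  }

  report <- list(arrays = per_array, families = families,
                 config = list(ref = config$ref, seed = config$seed))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
  }
  if (length(arrays) == 0) warning("empty input: no arrays analyzed")
  report
}

.pipeline_one <- function(arr, config, cset, out_dir) {
  norm <- normalize_orientation(arr, config$ref, config$align)
  monomers <- segment_monomers(norm, config$ref, config$segmentation,
                               normalize = FALSE)
  monomers <- classify_monomers(monomers, cset, params = config$align)
  usable <- monomers[!monomers$partial, , drop = FALSE]

  hor <- detect_hor(usable, config$hor, config$align)
  assigns <- lapply(usable$sequence, assign_monomer_sf, cset = cset,
                    params = config$align)
  sfa <- assign_array_sf(assigns, hor, cset, config$majority,
                         config$require_order)

  long <- detect_long_monomers(monomers, config$long_min_len)
  ins_reports <- lapply(long$sequence, function(s) {
    rep <- suppressWarnings(characterize_insertion(s, params = config$align))
    rep[c("monomer_length", "net_insertion", "dup_unit_len", "copies",
          "box_break_pos", "regenerated_box_core_intact")]
  })

  if (!is.null(out_dir)) {
    write_annotations(monomers_as_annotations(monomers),
                      file.path(out_dir, paste0(arr$id, ".monomers.bed")),
                      "BED")
    utils::write.table(
      as.data.frame(monomers)[, c("array_id", "index", "start", "end",
                                  "length", "partial", "ab_type", "dist_A",
                                  "dist_B", "motif", "motif_offset",
                                  "motif_mismatches", "core_intact",
                                  "full_intact")],
      file.path(out_dir, paste0(arr$id, ".classify.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ab <- table(factor(usable$ab_type, levels = c("A", "B", "undetermined")))
  list(
    monomers = monomers,
    report = list(
      id = arr$id,
      orientation = norm$orientation,
      n_monomers = nrow(usable),
      hor = list(period = hor$period, label = hor$label,
                 d_at_period = hor$d_at_period, n_units = hor$n_units),
      sf = list(family = sfa$sf, order_match = sfa$order_match),
      ab_counts = as.list(ab),
      insertions = ins_reports))
}
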