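# Plain-text readers and writers for the pipeline's data types.

#' Write / read a dose plate as tidy CSV
#'
#' Columns: `pdo_id`, `drug`, `dose_uM`, `replicate`, `viability_pct`. A file
#' may hold several plates; [read_dose_plates()] returns a list of
#' [dose_plate()] objects keyed by `pdo_id`.
#'
#' @param plates a `dose_plate` or list of them.
#' @param path CSV path.
#' @return `write_dose_plates()` returns `path` invisibly.
#' @export
write_dose_plates <- function(plates, path) {
  if (inherits(plates, "dose_plate")) plates <- list(plates)
  rows <- do.call(rbind, lapply(plates, function(p) {
    data.frame(pdo_id = p$pdo_id, drug = p$drug,
               dose_uM = rep(p$doses, times = ncol(p$viability)),
               replicate = rep(seq_len(ncol(p$viability)),
                               each = length(p$doses)),
               viability_pct = as.vector(p$viability))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_plates
#' @export
read_dose_plates <- function(path) {
  x <- read.csv(path)
  lapply(split(x, x$pdo_id), function(d) {
    doses <- sort(unique(d$dose_uM))
    reps <- sort(unique(d$replicate))
    v <- matrix(NA_real_, length(doses), length(reps))
    v[cbind(match(d$dose_uM, doses), match(d$replicate, reps))] <-
      d$viability_pct
    dose_plate(pdo_id = d$pdo_id[1], drug = d$drug[1], doses = doses,
               viability = v)
  })
}

#' Write / read a labeled count matrix
#'
#' The counts go to a TSV whose first column is `feature_id` followed by one
#' column per sample; the labels go to a two-column CSV (`sample_id`,
#' `label`).
#'
#' @param x a [count_matrix()].
#' @param counts_path,labels_path file paths.
#' @return `write_count_matrix()` returns `counts_path` invisibly.
#' @export
write_count_matrix <- function(x, counts_path, labels_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(feature_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(data.frame(sample_id = colnames(x$counts),
                       label = as.character(x$labels)),
            labels_path, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, labels_path) {
  tab <- read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  lab <- read.csv(labels_path)
  count_matrix(m, labels = lab$label[match(colnames(m), lab$sample_id)])
}

#' Write / read a xenograft tumor course (long CSV)
#'
#' Columns: `mouse_id`, `arm`, `day`, `volume_mm3`.
#'
#' @param course a [tumor_course()].
#' @param path CSV path.
#' @return `write_tumor_course()` returns `path` invisibly.
#' @export
write_tumor_course <- function(course, path) {
  stopifnot(inherits(course, "tumor_course"))
  write.csv(as.data.frame(course), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tumor_course
#' @export
read_tumor_course <- function(path) tumor_course(read.csv(path))

#' Write / read a patient cohort (CSV)
#'
#' Columns: `patient_id`, `pdo_class`, optionally `category`, `outcome`.
#'
#' @param cohort a `pdo_cohort` data frame.
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path)
  class(out) <- c("pdo_cohort", "data.frame")
  out
}

#' Write / read reference rank profiles (TSV rank matrix)
#'
#' The on-disk format is GCT-like: a feature x perturbagen matrix of integer
#' ranks (1 = most up-regulated), first column `feature_id`.
#'
#' @param profiles a `reference_profiles` list of ranked feature vectors.
#' @param path TSV path.
#' @return `write_reference_profiles()` returns `path` invisibly.
#' @export
write_reference_profiles <- function(profiles, path) {
  feats <- sort(unique(unlist(profiles)))
  ranks <- vapply(profiles, function(p) match(feats, p), numeric(length(feats)))
  tab <- data.frame(feature_id = feats, ranks, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_profiles
#' @export
read_reference_profiles <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  feats <- tab[[1]]
  prof <- lapply(tab[-1], function(r) feats[order(r)])
  structure(prof, class = "reference_profiles")
}

#' Export signature files for connectivity queries
#'
#' Writes the up- and down-regulated members of a feature set as two plain
#' text files (one feature per line, ordered by decreasing |statistic|) and
#' the full ranked table as a two-column `.rnk`-style TSV (feature, signed
#' statistic, descending).
#'
#' @param de a differential-expression table from [de_rank()].
#' @param features the signature features (subset of `de$feature_id`).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the named character vector of the three paths
#'   (`up`, `down`, `rnk`).
#' @export
write_signature_files <- function(de, features, dir, prefix = "signature") {
  stopifnot(all(features %in% de$feature_id))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sub <- de[match(features, de$feature_id), ]
  up <- sub$feature_id[order(-sub$stat)][sub$log2fc[order(-sub$stat)] > 0]
  down <- sub$feature_id[order(sub$stat)][sub$log2fc[order(sub$stat)] < 0]
  paths <- c(up = file.path(dir, paste0(prefix, "_up.txt")),
             down = file.path(dir, paste0(prefix, "_down.txt")),
             rnk = file.path(dir, paste0(prefix, ".rnk")))
  writeLines(up, paths[["up"]])
  writeLines(down, paths[["down"]])
  rnk <- de[order(-de$stat), c("feature_id", "stat")]
  write.table(rnk, paths[["rnk"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
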