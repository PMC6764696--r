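# Tab-separated readers and writers for the pipeline's file formats.
# All files are UTF-8 TSV with a header row; gene identifiers are opaque
# strings.

#' Write a genes-x-samples matrix as TSV
#'
#' @param x Numeric matrix with rownames.
#' @param path Output path.
#' @param id Name of the identifier column (default `"gene_id"`).
#' @export
write_matrix_tsv <- function(x, path, id = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-x-samples matrix from TSV
#'
#' @param path Input path.
#' @param id Name of the identifier column.
#' @return Numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path, id = "gene_id") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rn <- df[[id]]
  m <- as.matrix(df[setdiff(names(df), id)])
  rownames(m) <- rn
  m
}

#' Write/read sample metadata (`sample_id`, `nutrient`, `growth_rate`)
#' @param meta Data.frame.
#' @param path Path.
#' @export
write_samples_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_tsv
#' @export
read_samples_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Write/read a directed edge list (`tf`, `target`)
#' @param network A `regulatory_network` or edge data.frame.
#' @param path Path.
#' @export
write_edges_tsv <- function(network, path) {
  edges <- if (inherits(network, "regulatory_network")) network$edges else network
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path)
  regulatory_network(utils::read.delim(path, stringsAsFactors = FALSE))

#' Write/read a sector partition
#' @param partition A `sector_partition`.
#' @param path Path.
#' @param nonspecific_min,invariant_min Thresholds restored on read.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path, nonspecific_min = 9, invariant_min = 4) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, nonspecific_min = nonspecific_min,
            invariant_min = invariant_min,
            class = c("sector_partition", "data.frame"))
}

#' Write a full synthetic dataset to a directory
#'
#' Writes every input the pipeline consumes: expression and sample
#' metadata, truth labels, network edges, compendium profiles and modifier
#' metadata, reference matrix, PA table with condition metadata, and the
#' score tracks.
#'
#' @param sim A `sector5_sim` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sector5_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_matrix_tsv(sim$expression$raw, fp("expression.tsv"))
  write_samples_tsv(sim$expression$meta, fp("samples.tsv"))
  utils::write.table(
    data.frame(gene_id = sim$truth$gene_id, sector = sim$truth$sector,
               stringsAsFactors = FALSE),
    fp("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_edges_tsv(sim$network, fp("network.tsv"))
  write_matrix_tsv(sim$compendium$profiles, fp("compendium.tsv"),
                   id = "modifier")
  utils::write.table(sim$compendium$mutants, fp("modifiers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sim$reference, fp("reference.tsv"))
  write_matrix_tsv(sim$pa$pa, fp("pa.tsv"))
  utils::write.table(
    data.frame(condition = colnames(sim$pa$pa),
               growth_rate = sim$pa$growth_rates, stringsAsFactors = FALSE),
    fp("pa_conditions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- data.frame(gene_id = names(sim$tracks$continuous[[1]]),
                   sim$tracks$continuous, sim$tracks$binary,
                   stringsAsFactors = FALSE)
  utils::write.table(tr, fp("tracks.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
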