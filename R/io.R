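#' Write / read ROI time series as TSV
#'
#' Rows are volumes, columns ROIs; the header row carries the ROI ids.
#'
#' @param ts matrix with ROI column names.
#' @param path output file.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(as.matrix(ts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @return \code{read_timeseries_tsv}: numeric matrix with ROI ids as
#'   column names; ragged rows or non-numeric cells are an error naming the
#'   offending column.
#' @export
read_timeseries_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  m <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  bad <- colSums(is.na(m)) > 0
  if (any(bad))
    stop(sprintf("non-numeric cells in column(s): %s",
                 paste(names(df)[bad], collapse = ", ")))
  dimnames(m) <- list(NULL, names(df))
  m
}

#' Write / read a weighted network as an edge-list TSV
#'
#' Columns \code{node_i}, \code{node_j}, \code{weight}, one header line;
#' weights are printed with 10 significant digits so a write/read/write
#' cycle is byte-identical.
#'
#' @param net \code{weighted_network}; @param path file path.
#' @export
write_edge_list <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d", net$n_nodes), con)
  writeLines("node_i\tnode_j\tweight", con)
  if (net$K > 0)
    writeLines(sprintf("%d\t%d\t%s", net$edges$i, net$edges$j,
                       formatC(net$edges$w, digits = 10, format = "g")), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  n_nodes <- as.integer(sub("# n_nodes=", "", lines[1], fixed = TRUE))
  if (length(lines) <= 2)
    return(weighted_network(n_nodes,
                            data.frame(i = integer(), j = integer(),
                                       w = numeric())))
  df <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                          col.names = c("i", "j", "w"))
  weighted_network(n_nodes, df)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Per-subject time-series and motion TSVs, a manifest TSV (subject id,
#' group, covariates) and the ground truth as JSON.
#'
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param dir output directory (created if absent).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_timeseries_tsv(s$timeseries,
                         file.path(dir, paste0(s$subject_id, "_ts.tsv")))
    utils::write.table(s$motion,
                       file.path(dir, paste0(s$subject_id, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- generate_clinical_table(cohort)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export BrainNet-style .node and .edge files
#'
#' .node: x, y, z, color (module id; flagged nodes get a distinct value),
#' size (nodal efficiency), label — six whitespace-separated columns.
#' .edge: the full square adjacency matrix, tab separated. Synthetic
#' layouts place nodes on a unit sphere.
#'
#' @param nodal data.frame from \code{\link{nodal_efficiency}}.
#' @param partition \code{partition} supplying module colors.
#' @param net \code{weighted_network} for the .edge matrix.
#' @param out_prefix path prefix; writes \code{<prefix>.node} and
#'   \code{<prefix>.edge}.
#' @param flagged optional node indices highlighted with color
#'   \code{n_modules + 1}.
#' @param coords optional n x 3 coordinate matrix; default unit-sphere
#'   (Fibonacci lattice) layout.
#' @export
write_brainnet_files <- function(nodal, partition, net, out_prefix,
                                 flagged = integer(), coords = NULL) {
  n <- nrow(nodal)
  if (is.null(coords)) {
    idx <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * idx / n)
    theta <- pi * (1 + sqrt(5)) * idx
    coords <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  color <- partition$labels
  color[flagged] <- partition$n_modules + 1L
  node <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                     color = color, size = nodal$e_nodal,
                     label = sprintf("roi_%04d", seq_len(n)))
  utils::write.table(node, paste0(out_prefix, ".node"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(adjacency_matrix(net), paste0(out_prefix, ".edge"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(out_prefix)
}
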