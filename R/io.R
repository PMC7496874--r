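#' Read a phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] / [ape::read.nexus()] that checks
#' branch lengths are present and nonnegative, and reports polytomies and
#' zero-length branches as messages (polytomy resolution is deferred to
#' the likelihood machinery, which is invariant to zero-length
#' resolutions).
#'
#' @param path file path.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse a tree from ", path)
  if (is.null(tree$edge.length))
    stop("tree in ", path, " has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree in ", path, " has negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("tree in ", path, " has duplicated tip labels")
  if (!ape::is.binary(tree) || tree$Nnode != length(tree$tip.label) - 1L)
    message("tree contains polytomies; they are handled as-is by the pruning")
  if (any(tree$edge.length == 0))
    message("tree contains zero-length branches")
  tree
}

#' Read a species trait table
#'
#' Delimited text with a header and columns `species`, `D` (binary
#' developmental mode) and either `E` (binary large-egg trait) or
#' `egg_size_mm` (continuous; dichotomization is left to
#' [dichotomize_egg_size()] so the threshold policy stays explicit).
#' Empty cells become missing values.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return data.frame with `species`, `D`, and `E` and/or `egg_size_mm`.
#' @export
read_trait_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  if (!"D" %in% names(df)) stop("trait table needs a 'D' column")
  if (anyDuplicated(df$species))
    stop("duplicated species label(s): ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  bad <- which(!is.na(df$D) & !df$D %in% c(0, 1))
  if (length(bad))
    stop("unparseable D values in row(s): ", paste(bad, collapse = ", "))
  if ("E" %in% names(df)) {
    bad <- which(!is.na(df$E) & !df$E %in% c(0, 1))
    if (length(bad))
      stop("unparseable E values in row(s): ", paste(bad, collapse = ", "))
  }
  if ("egg_size_mm" %in% names(df)) {
    suppressWarnings(df$egg_size_mm <- as.numeric(df$egg_size_mm))
    bad <- which(!is.na(df$egg_size_mm) & df$egg_size_mm < 0)
    if (length(bad))
      stop("negative egg sizes in row(s): ", paste(bad, collapse = ", "))
  }
  if (!any(c("E", "egg_size_mm") %in% names(df)))
    stop("trait table needs an 'E' or 'egg_size_mm' column")
  df
}

#' Write result tables with a reproducibility manifest
#'
#' Writes each table as CSV with a deterministic column order and a
#' `manifest.json` recording the seed, the configuration used and an MD5
#' checksum of every written file, so any stochastic run can be re-created
#' from its manifest.
#'
#' @param tables named list of data.frames.
#' @param outdir output directory (created if absent).
#' @param seed the seed that produced the tables.
#' @param config a list describing the run configuration.
#' @return invisible character vector of written file paths.
#' @export
write_results <- function(tables, outdir, seed, config = list()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    df <- df[, sort(names(df)), drop = FALSE]
    fp <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(df, fp, row.names = FALSE)
    paths <- c(paths, fp)
  }
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("ddevo")),
    config = config,
    files = lapply(setNames(paths, basename(paths)),
                   function(f) unname(tools::md5sum(f))))
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mf))
}
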