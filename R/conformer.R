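#' Construct a conformer
#'
#' A conformer is a molecule as a 3D point set plus a bond graph: element
#' symbols, n x 3 Cartesian coordinates in Angstrom, and an undirected bond
#' list. Atomic property weights (van der Waals volume, polarizability,
#' electrotopological state), each scaled relative to carbon, are attached
#' from the packaged table; hydrogens are used only if explicitly present —
#' none are ever added implicitly.
#'
#' @param elements Character vector of element symbols.
#' @param coords n x 3 numeric matrix, Angstrom.
#' @param bonds Two-column integer matrix of bonded atom index pairs
#'   (undirected; self-loops forbidden).
#' @return An object of class `conformer`.
#' @export
conformer <- function(elements, coords, bonds) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3, all(is.finite(coords)))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds >= 1), all(bonds <= n))
    if (any(bonds[, 1] == bonds[, 2])) stop("self-loops are not allowed")
  }
  tab <- atomic_weight_table()
  unknown <- setdiff(unique(elements), rownames(tab))
  if (length(unknown) > 0) {
    stop("no atomic weights for element(s): ",
         paste(unknown, collapse = ", "))
  }
  structure(list(elements = elements, coords = coords, bonds = bonds),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("conformer:", length(x$elements), "atoms,", nrow(x$bonds), "bonds\n")
  invisible(x)
}

# packaged carbon-scaled atomic property table, cached per session
atomic_weight_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "atomic_weights.csv",
                          package = "bitterQSBR", mustWork = TRUE)
      tab <- utils::read.csv(path, stringsAsFactors = FALSE)
      rownames(tab) <- tab$element
      cache <<- tab
    }
    cache
  }
})

#' Per-atom weights for a weighting scheme
#'
#' Scheme "u" is unit weights; "v", "p", "s" are van der Waals volume,
#' polarizability and electrotopological state, carbon-scaled, from the
#' packaged table.
#'
#' @param conf A [conformer()].
#' @param weight One of "u", "v", "p", "s".
#' @return Numeric vector of per-atom weights.
#' @export
atom_weights <- function(conf, weight = c("u", "v", "p", "s")) {
  weight <- match.arg(weight)
  if (weight == "u") return(rep(1, length(conf$elements)))
  col <- c(v = "vdw_volume", p = "polarizability", s = "estate")[[weight]]
  atomic_weight_table()[conf$elements, col]
}

# adjacency matrix of the bond graph
adjacency_matrix <- function(conf) {
  n <- length(conf$elements)
  a <- matrix(0L, n, n)
  if (nrow(conf$bonds) > 0) {
    a[conf$bonds] <- 1L
    a[conf$bonds[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

# all-pairs shortest topological distances (Inf when disconnected)
topological_distances <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  igraph::distances(g)
}

#' Read a conformer from an XYZ file with a sidecar bond list
#'
#' Standard XYZ layout (atom count, comment, `element x y z` rows) plus a
#' two-column whitespace-separated bond file; pass `bonds_path = NULL` for a
#' bond-free point set.
#'
#' @param path XYZ file path.
#' @param bonds_path Bond-list path or NULL.
#' @return A [conformer()].
#' @export
read_xyz_conformer <- function(path, bonds_path = NULL) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  elements <- vapply(rows, `[[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  bonds <- if (is.null(bonds_path)) matrix(integer(0), 0, 2) else
    as.matrix(utils::read.table(bonds_path))
  conformer(elements, coords, bonds)
}

#' Write a conformer as XYZ plus a sidecar bond list
#'
#' @param conf A [conformer()].
#' @param path XYZ output path.
#' @param bonds_path Bond-list output path (default `<path>.bonds`).
#' @return `path`, invisibly.
#' @export
write_xyz_conformer <- function(conf, path,
                                bonds_path = paste0(path, ".bonds")) {
  n <- length(conf$elements)
  body <- sprintf("%s %.6f %.6f %.6f", conf$elements,
                  conf$coords[, 1], conf$coords[, 2], conf$coords[, 3])
  writeLines(c(as.character(n), "generated by bitterQSBR", body), path)
  utils::write.table(conf$bonds, bonds_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read the first molecule of an SDF file as a conformer
#'
#' Parsing is delegated to ChemmineR; coordinates and the bond block are
#' converted to the package's conformer container.
#'
#' @param path SDF (V2000) file path.
#' @return A [conformer()].
#' @export
read_sdf_conformer <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF requires the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (nrow(bb) > 0) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
           else matrix(integer(0), 0, 2)
  conformer(elements, ab[, 1:3], bonds)
}
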