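#' Gene-set (protein-set) libraries
#'
#' A `gene_set_library` is a named, ordered collection of protein sets — the
#' prior-knowledge substrate from which bipartite protein/set graphs are
#' built. Sets are stored as a named list of character vectors of protein
#' identifiers. Identifiers are opaque strings; any gene-to-protein mapping
#' is the caller's responsibility.
#'
#' @param sets Named list of character vectors (set id -> member proteins).
#'   Set ids must be unique, every set non-empty, members unique within a set.
#' @param name Text label for the library.
#' @return A `gene_set_library` object.
#' @examples
#' lib <- gene_set_library(list(S1 = c("A", "B"), S2 = c("B", "C", "D")))
#' set_sizes(lib)
#' @export
gene_set_library <- function(sets, name = "library") {
  stopifnot(is.list(sets))
  ids <- names(sets)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every set must have a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate set ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(m) as.character(m))
  if (any(lengths(sets) == 0L)) stop("empty member list in library", call. = FALSE)
  if (any(vapply(sets, anyDuplicated, 0L) > 0L)) {
    stop("duplicate members within a set", call. = FALSE)
  }
  structure(list(name = as.character(name)[1], sets = sets),
            class = "gene_set_library")
}

#' @export
length.gene_set_library <- function(x) length(x$sets)

#' @export
print.gene_set_library <- function(x, ...) {
  sz <- set_sizes(x)
  cat("<gene_set_library> ", x$name, ": ", length(x), " sets",
      if (length(x)) paste0(", sizes ", min(sz), "-", max(sz)), "\n", sep = "")
  invisible(x)
}

#' Set sizes of a library
#' @param lib A `gene_set_library`.
#' @return Named integer vector of member counts.
#' @export
set_sizes <- function(lib) {
  stopifnot(inherits(lib, "gene_set_library"))
  lengths(lib$sets)
}

#' Protein panels
#'
#' A protein panel is the ordered list of unique protein identifiers whose
#' ordering defines the feature layout of every downstream artifact
#' (expression columns, graph protein nodes, embeddings).
#'
#' @param proteins Character vector of identifiers.
#' @return The validated character vector.
#' @export
protein_panel <- function(proteins) {
  proteins <- as.character(proteins)
  if (length(proteins) == 0L) stop("empty protein panel", call. = FALSE)
  if (anyNA(proteins) || any(proteins == "")) stop("blank protein identifier", call. = FALSE)
  if (anyDuplicated(proteins)) {
    stop("duplicate protein identifiers in panel", call. = FALSE)
  }
  proteins
}

#' Read a GMT gene-set file
#'
#' GMT is tab-separated, one set per line: set id, description, then member
#' identifiers. The description column is discarded; duplicate members
#' within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @param name Library label; defaults to the file name.
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], " (fewer than 3 tab-separated fields) in ",
         path, call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, function(m) length(m) - length(unique(m)), 0L))
  if (ndup > 0L) {
    warning(ndup, " duplicate member(s) within GMT lines were dropped", call. = FALSE)
    sets <- lapply(sets, unique)
  }
  names(sets) <- ids
  gene_set_library(sets, name = name)
}

#' Write a library to GMT
#'
#' Emits the GMT dialect with a literal `"NA"` description field, one set
#' per line in library order. An empty library yields a zero-byte file.
#'
#' @param lib A `gene_set_library`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "gene_set_library"))
  lines <- vapply(seq_along(lib$sets), function(i) {
    paste(c(names(lib$sets)[i], "NA", lib$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter a library against a protein panel
#'
#' Intersects every set with the measured panel and keeps a set iff its
#' intersection size lies in `[min_size, max_size]` — the size window used
#' when building graphs from curated ontology libraries. Idempotent.
#'
#' @param lib A `gene_set_library`.
#' @param panel Character vector of measured protein identifiers.
#' @param min_size,max_size Inclusive bounds on the panel-intersected set
#'   size. Defaults 2 and 100.
#' @return A filtered `gene_set_library` whose sets contain only panel
#'   proteins. May be empty.
#' @export
filter_library <- function(lib, panel, min_size = 2, max_size = 100) {
  stopifnot(inherits(lib, "gene_set_library"))
  panel <- protein_panel(panel)
  kept <- lapply(lib$sets, function(m) m[m %in% panel])
  keep <- lengths(kept) >= min_size & lengths(kept) <= max_size
  out <- structure(list(name = lib$name, sets = kept[keep]),
                   class = "gene_set_library")
  out
}

#' Random protein-label permutation
#'
#' Draws a uniformly random bijection panel -> panel. Applying it to set
#' members (or expression columns) before graph construction destroys the
#' protein-to-set correspondence while preserving every degree and set
#' size — the capacity-matched permuted null control.
#'
#' @param panel Protein panel (character).
#' @param seed Integer seed; the same seed always yields the same mapping.
#' @param identity If `TRUE`, return the identity mapping (for control
#'   checks that a permuted build with the identity equals the informed one).
#' @return Named character vector: `names()` are the original identifiers,
#'   values the relabeled ones.
#' @export
permute_protein_labels <- function(panel, seed, identity = FALSE) {
  panel <- protein_panel(panel)
  if (length(panel) < 2L) stop("panel of size < 2: permutation is meaningless", call. = FALSE)
  if (identity) {
    perm <- panel
  } else {
    perm <- with_seed(seed, sample(panel))
  }
  names(perm) <- panel
  perm
}

#' Apply a protein-label permutation to a library
#'
#' Relabels every member through the bijection from
#' [permute_protein_labels()]. Set sizes and hence all graph degrees are
#' preserved exactly.
#'
#' @param lib A `gene_set_library` whose members are all in `names(perm)`.
#' @param perm Named character bijection.
#' @return The relabeled `gene_set_library`.
#' @export
permute_library <- function(lib, perm) {
  stopifnot(inherits(lib, "gene_set_library"))
  missing <- setdiff(unique(unlist(lib$sets, use.names = FALSE)), names(perm))
  if (length(missing)) {
    stop("library members not covered by the permutation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(lib$sets, function(m) unname(perm[m]))
  structure(list(name = paste0(lib$name, "_permuted"), sets = sets),
            class = "gene_set_library")
}

#' Uniform random set library
#'
#' Generates `n_sets` random protein sets whose sizes are drawn from a
#' discrete uniform distribution on `[size_min, size_max]` and whose members
#' are sampled uniformly at random without replacement — the random-graph
#' null used to control for model size (default 200 sets of 2-20 proteins).
#'
#' @param panel Protein panel.
#' @param n_sets Number of sets (default 200).
#' @param size_min,size_max Inclusive size bounds (defaults 2 and 20).
#' @param seed Integer seed.
#' @return A `gene_set_library` with machine-generated set ids.
#' @export
make_uniform_random_library <- function(panel, n_sets = 200, size_min = 2,
                                        size_max = 20, seed = 1) {
  panel <- protein_panel(panel)
  stopifnot(n_sets >= 1, size_min >= 1, size_max >= size_min)
  if (size_max > length(panel)) {
    stop("size_max exceeds panel size (", length(panel), ")", call. = FALSE)
  }
  sets <- with_seed(seed, {
    sizes <- size_min + sample.int(size_max - size_min + 1L, n_sets,
                                   replace = TRUE) - 1L
    lapply(sizes, function(s) sample(panel, s))
  })
  names(sets) <- sprintf("RND_U%04d", seq_len(n_sets))
  gene_set_library(sets, name = "uniform_random")
}

#' Fit a shifted-geometric model to reference set sizes
#'
#' Maximum-likelihood fit of `size = support_min + G`, `G ~ Geom(p)` on
#' `{0, 1, ...}`, to the empirical set sizes of a reference library (e.g. a
#' curated cellular-component library). The MLE is
#' `p = 1 / (1 + mean(size) - support_min)`.
#'
#' @param ref A `gene_set_library` whose set sizes are all `>= support_min`.
#' @param support_min Smallest admissible set size (default 2).
#' @return The success probability `p` in (0, 1].
#' @export
fit_geometric_size_model <- function(ref, support_min = 2) {
  stopifnot(inherits(ref, "gene_set_library"))
  sz <- set_sizes(ref)
  if (length(sz) == 0L) stop("empty reference library", call. = FALSE)
  if (any(sz < support_min)) {
    stop("reference set sizes below support_min = ", support_min, call. = FALSE)
  }
  1 / (1 + mean(sz) - support_min)
}

#' Geometric random set library
#'
#' Random sets whose sizes follow the shifted geometric
#' `support_min + Geom(p)` (truncated at the panel size) with members
#' assigned uniformly at random without replacement. Used for the graph
#' density sweep, with `p` fitted to a curated reference library.
#'
#' @param panel Protein panel.
#' @param n_sets Number of sets.
#' @param p Geometric success probability in (0, 1].
#' @param support_min Smallest set size (default 2).
#' @param seed Integer seed.
#' @return A `gene_set_library`.
#' @export
make_geometric_random_library <- function(panel, n_sets, p, support_min = 2,
                                          seed = 1) {
  panel <- protein_panel(panel)
  if (n_sets <= 0) stop("n_sets must be positive", call. = FALSE)
  if (!(p > 0 && p <= 1)) stop("p must be in (0, 1]", call. = FALSE)
  sets <- with_seed(seed, {
    sizes <- support_min + stats::rgeom(n_sets, p)
    sizes <- pmin(sizes, length(panel))
    lapply(sizes, function(s) sample(panel, s))
  })
  names(sets) <- sprintf("RND_G%04d", seq_len(n_sets))
  gene_set_library(sets, name = "geometric_random")
}
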