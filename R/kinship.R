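## Pedigree kinship coefficients and relative enumeration.
##
## Kinship phi(i, j) is the probability that a random allele drawn from i is
## identical by descent to a random allele drawn from j.  Founders are
## assumed mutually unrelated; inbreeding arising from user-supplied
## pedigrees is handled by the standard recursion phi(i, i) =
## (1 + phi(father, mother)) / 2.

#' Build a pedigree graph
#'
#' @param pedigree A data.frame/data.table with columns `id`, `father_id`,
#'   `mother_id` (`NA` parents mark founders).
#' @return A `pedigree_graph` with parent indices and a topological order
#'   (parents precede children). Stops on cycles or unknown parent ids.
#' @export
pedigree_graph <- function(pedigree) {
  ped <- as.data.table(pedigree)
  stopifnot(all(c("id", "father_id", "mother_id") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  n <- nrow(ped)
  id <- ped$id
  fa <- match(ped$father_id, id)
  mo <- match(ped$mother_id, id)
  if (any(!is.na(ped$father_id) & is.na(fa)))
    stop("father_id not present in pedigree id column")
  if (any(!is.na(ped$mother_id) & is.na(mo)))
    stop("mother_id not present in pedigree id column")
  ## generation depth by fixed-point sweeps; a cycle never converges
  depth <- rep(0L, n)
  for (it in seq_len(n + 1L)) {
    pd <- pmax(ifelse(is.na(fa), -1L, depth[ifelse(is.na(fa), 1L, fa)]),
               ifelse(is.na(mo), -1L, depth[ifelse(is.na(mo), 1L, mo)])) + 1L
    if (all(pd == depth)) break
    if (it > n) stop("pedigree contains a cycle")
    depth <- pd
  }
  structure(list(id = id, father = fa, mother = mo, depth = depth,
                 order = order(depth)),
            class = "pedigree_graph")
}

#' @export
print.pedigree_graph <- function(x, ...) {
  cat("<pedigree_graph> ", length(x$id), " members, ",
      sum(is.na(x$father) & is.na(x$mother)), " founders, max depth ",
      max(x$depth), "\n", sep = "")
  invisible(x)
}

.graph_pos <- function(graph, ids) {
  pos <- match(ids, graph$id)
  if (anyNA(pos)) stop("unknown id(s): ",
                       paste(ids[is.na(pos)], collapse = ", "))
  pos
}

#' Kinship coefficient between two pedigree members
#'
#' Standard recursive kinship with memoization: phi(i, i) =
#' (1 + phi(f_i, m_i)) / 2 (0.5 for non-inbred), and for i != j with i the
#' generationally later individual, phi(i, j) =
#' (phi(f_i, j) + phi(m_i, j)) / 2; founders are unrelated to everyone
#' except their own descendants.
#'
#' @param graph A [pedigree_graph()].
#' @param i,j Person ids.
#' @return Kinship coefficient in `[0, 0.5]` (above 0.5 only under
#'   inbreeding of `i == j`).
#' @export
kinship <- function(graph, i, j) {
  stopifnot(inherits(graph, "pedigree_graph"))
  pi <- .graph_pos(graph, i)
  pj <- .graph_pos(graph, j)
  memo <- new.env(parent = emptyenv())
  .phi_rec(graph, pi, pj, memo)
}

.phi_rec <- function(g, a, b, memo) {
  if (is.na(a) || is.na(b)) return(0)
  key <- if (a <= b) paste0(a, ".", b) else paste0(b, ".", a)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (a == b) {
    0.5 * (1 + .phi_rec(g, g$father[a], g$mother[a], memo))
  } else {
    ## recurse on the generationally later member; it cannot be an
    ## ancestor of the other
    if (g$depth[a] < g$depth[b]) { tmp <- a; a <- b; b <- tmp }
    if (is.na(g$father[a]) && is.na(g$mother[a])) 0
    else 0.5 * (.phi_rec(g, g$father[a], b, memo) +
                  .phi_rec(g, g$mother[a], b, memo))
  }
  memo[[key]] <- val
  val
}

#' Full kinship matrix of a pedigree
#'
#' The tabular method: members are processed in topological order and each
#' new row is the parent-row average, with diagonal (1 + phi(f, m)) / 2.
#' Intended for pedigrees up to a few thousand members; the batch link
#' builder applies it per connected component.
#'
#' @param graph A [pedigree_graph()].
#' @return Symmetric matrix with ids as dimnames.
#' @export
kinship_matrix <- function(graph) {
  stopifnot(inherits(graph, "pedigree_graph"))
  n <- length(graph$id)
  K <- matrix(0, n, n, dimnames = list(graph$id, graph$id))
  ord <- graph$order
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- graph$father[i]; m <- graph$mother[i]
    if (is.na(f) && is.na(m)) {
      K[i, i] <- 0.5
    } else {
      prev <- ord[seq_len(k - 1L)]
      rf <- if (is.na(f)) 0 else K[f, prev]
      rm_ <- if (is.na(m)) 0 else K[m, prev]
      row <- 0.5 * (rf + rm_)
      K[i, prev] <- row
      K[prev, i] <- row
      K[i, i] <- 0.5 * (1 + if (is.na(f) || is.na(m)) 0 else K[f, m])
    }
  }
  K
}

## Connected-component labels via min-label propagation over parent-child
## edges; converges in O(component diameter) vectorized sweeps.
.components <- function(graph) {
  n <- length(graph$id)
  lab <- seq_len(n)
  edge_child <- c(which(!is.na(graph$father)), which(!is.na(graph$mother)))
  edge_parent <- c(graph$father[!is.na(graph$father)],
                   graph$mother[!is.na(graph$mother)])
  ## undirected edges, both orientations; duplicated targets are handled
  ## by grouped minima so no update can overwrite another
  src <- c(edge_parent, edge_child)
  tgt <- c(edge_child, edge_parent)
  repeat {
    mins <- data.table(t = tgt, l = lab[src])[, min(l), by = t]
    new <- lab
    new[mins$t] <- pmin(new[mins$t], mins$V1)
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab, unique(lab))
}

.degree_bin <- function(relatedness, max_degree = 5L) {
  pmin(pmax(as.integer(round(-log2(relatedness))), 1L), max_degree)
}

#' Enumerate a proband's 1st- to 5th-degree relatives
#'
#' All pedigree members (excluding the proband) with relatedness
#' `2 * phi >= 2^-max_degree`. Degree is the nearest power-of-two bin of the
#' relatedness on the log2 scale (0.5 -> 1, 0.25 -> 2, ..., 0.03125 -> 5),
#' so parent and full sib are both degree 1 and first cousins degree 3.
#'
#' @param graph A [pedigree_graph()].
#' @param proband Person id.
#' @param max_degree Maximum degree (default 5).
#' @param cohab Optional cohabitation table (`id_a`, `id_b`, `years`);
#'   pairs absent from it get 0 co-residence years.
#' @return data.table with columns proband, relative, phi, relatedness,
#'   degree, cohab_years.
#' @export
enumerate_relatives <- function(graph, proband, max_degree = 5L,
                                cohab = NULL) {
  stopifnot(inherits(graph, "pedigree_graph"))
  .graph_pos(graph, proband)
  relative_links(graph, proband, max_degree = max_degree, cohab = cohab)
}

#' Relative links for a set of probands
#'
#' Batch version of [enumerate_relatives()]: computes, per connected
#' pedigree component, the full kinship matrix by the tabular method and
#' extracts every (proband, relative) pair at or above the relatedness
#' threshold.
#'
#' @param graph A [pedigree_graph()].
#' @param probands Ids of probands (e.g. [cohort_ids()]).
#' @param max_degree Maximum relative degree retained (default 5).
#' @param cohab Optional cohabitation table; unlisted pairs get 0 years.
#' @return data.table(proband, relative, phi, relatedness, degree,
#'   cohab_years) sorted by proband.
#' @export
relative_links <- function(graph, probands, max_degree = 5L, cohab = NULL) {
  stopifnot(inherits(graph, "pedigree_graph"))
  ppos <- .graph_pos(graph, probands)
  thresh <- 2^(-max_degree)
  labs <- .components(graph)
  is_prob <- logical(length(graph$id))
  is_prob[ppos] <- TRUE
  comp_with_prob <- unique(labs[ppos])

  out_p <- vector("list", length(comp_with_prob))
  out_r <- vector("list", length(comp_with_prob))
  out_phi <- vector("list", length(comp_with_prob))
  for (k in seq_along(comp_with_prob)) {
    members <- which(labs == comp_with_prob[k])
    sub <- data.table(id = graph$id[members],
                      father_id = graph$id[graph$father[members]],
                      mother_id = graph$id[graph$mother[members]])
    Ksub <- kinship_matrix(pedigree_graph(sub))
    rel <- 2 * Ksub
    diag(rel) <- 0
    pm <- which(is_prob[members])
    hits <- which(rel[pm, , drop = FALSE] >= thresh, arr.ind = TRUE)
    if (nrow(hits)) {
      out_p[[k]] <- sub$id[pm[hits[, 1L]]]
      out_r[[k]] <- sub$id[hits[, 2L]]
      out_phi[[k]] <- Ksub[cbind(pm[hits[, 1L]], hits[, 2L])]
    }
  }
  links <- data.table(proband = unlist(out_p), relative = unlist(out_r),
                      phi = unlist(out_phi))
  if (nrow(links) == 0L)
    links <- data.table(proband = integer(), relative = integer(),
                        phi = numeric())
  links[, relatedness := 2 * phi]
  links[, degree := .degree_bin(relatedness, max_degree)]
  links[, cohab_years := 0]
  if (!is.null(cohab) && nrow(links)) {
    cb <- as.data.table(cohab)
    cb <- cb[, .(lo = pmin(id_a, id_b), hi = pmax(id_a, id_b), years)]
    links[, `:=`(lo = pmin(proband, relative),
                 hi = pmax(proband, relative))]
    links[cb, cohab_years := i.years, on = c("lo", "hi")]
    links[, c("lo", "hi") := NULL]
  }
  setorder(links, proband, relative)
  links[]
}
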