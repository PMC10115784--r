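# Rooted-topology census over anchor gene trees. Tips are mapped to the
# roles O (outgroup), T1/T2 (tetraploid subgenomes), P1..P4 (octoploid
# subgenomes); the canonical form of a rooted leaf-labeled topology is
# invariant under child-order permutation.

# nested representation: a leaf is a role string, an internal node a list
# of children.
canon_nested <- function(x) {
  if (is.character(x)) return(list(str = x, minrole = x))
  kids <- lapply(x, canon_nested)
  ord <- order(vapply(kids, `[[`, character(1), "minrole"))
  kids <- kids[ord]
  list(str = paste0("(", paste(vapply(kids, `[[`, character(1), "str"),
                               collapse = ","), ")"),
       minrole = kids[[1]]$minrole)
}

phylo_to_nested <- function(tree, roles) {
  unmapped <- setdiff(tree$tip.label, names(roles))
  if (length(unmapped))
    stop("unmapped tip(s): ", paste(unmapped, collapse = ","))
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(unname(roles[tree$tip.label[node]]))
    lapply(children[[as.character(node)]], rec)
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  rec(root)
}

#' Canonical string of a rooted leaf-labeled topology
#'
#' Branch lengths are discarded; children are sorted by the
#' lexicographically smallest role they contain, so trees identical up to
#' sibling order yield identical strings.
#'
#' @param tree rooted `phylo`.
#' @param roles named character vector mapping tip labels to roles.
#' @return canonical topology string.
#' @export
canonicalize_topology <- function(tree, roles) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  canon_nested(phylo_to_nested(tree, roles))$str
}

#' Topology classes predicted by the competing polyploidy models
#'
#' Under the nested whole-genome-duplication (WGD) model the octoploid
#' carries two sister-pairs of homoeologous subgenomes, each pair sister
#' to one tetraploid subgenome: rooted shape
#' `(O,((Ti,(Pa,Pb)),(Tj,(Pc,Pd))))`. Under the reticulate
#' allopolyploidization model each tetraploid subgenome is sister to the
#' octoploid subgenome sharing its progenitor, one remaining octoploid
#' subgenome attaches to the first such pair, and the last is sister to
#' the outgroup-adjacent position: rooted shape
#' `(O,((((Ti,Pa),Pb),(Tj,Pc)),Pd))`. All assignments of concrete
#' subgenome labels to the shape are enumerated; the two sets are
#' disjoint.
#'
#' @param model `"WGD"` or `"reticulate"`.
#' @return character vector of canonical topology strings.
#' @export
model_predicted_classes <- function(model = c("WGD", "reticulate")) {
  model <- match.arg(model)
  Ts <- c("T1", "T2")
  Ps <- c("P1", "P2", "P3", "P4")
  out <- character(0)
  if (model == "WGD") {
    pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                     list(c(1, 4), c(2, 3)))
    for (pr in pairings) for (tperm in list(c(1, 2), c(2, 1))) {
      ingroup <- list(
        list(Ts[tperm[1]], list(Ps[pr[[1]][1]], Ps[pr[[1]][2]])),
        list(Ts[tperm[2]], list(Ps[pr[[2]][1]], Ps[pr[[2]][2]])))
      out <- c(out, canon_nested(list("O", ingroup))$str)
    }
  } else {
    perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
    for (i in seq_len(nrow(perms))) for (tperm in list(c(1, 2), c(2, 1))) {
      p <- perms[i, ]
      ingroup <- list(
        list(list(list(Ts[tperm[1]], Ps[p[1]]), Ps[p[2]]),
             list(Ts[tperm[2]], Ps[p[3]])),
        Ps[p[4]])
      out <- c(out, canon_nested(list("O", ingroup))$str)
    }
  }
  unique(out)
}

#' Census of rooted gene-tree topologies with model tags
#'
#' Counts canonical rooted topologies over the role-labeled anchor trees
#' and tags each class as WGD-like, reticulate-like or other via
#' [model_predicted_classes()]. Trees are rooted on the tip carrying role
#' `O` if not already rooted there.
#'
#' @param trees list of `phylo` anchor gene trees.
#' @param roles named character vector, tip label -> role (`O`, `T1`,
#'   `T2`, `P1`..`P4`).
#' @return object of class `topology_census`: list with `classes`
#'   (data.frame class/count/fraction/model, ranked by count), `total`,
#'   and `verdict` (model tag of the plurality class).
#' @export
census <- function(trees, roles) {
  strs <- vapply(trees, function(tr) {
    og <- tr$tip.label[roles[tr$tip.label] == "O"]
    if (length(og) != 1) stop("each tree needs exactly one outgroup tip")
    tr <- root_on_outgroup(tr, og)
    canonicalize_topology(tr, roles)
  }, character(1))
  tab <- sort(table(strs), decreasing = TRUE)
  wgd <- model_predicted_classes("WGD")
  ret <- model_predicted_classes("reticulate")
  cls <- data.frame(class = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / length(strs),
                    stringsAsFactors = FALSE)
  cls$model <- ifelse(cls$class %in% wgd, "WGD-model",
                      ifelse(cls$class %in% ret, "reticulate-model", "other"))
  structure(list(classes = cls, total = length(strs),
                 verdict = cls$model[1]),
            class = "topology_census")
}

#' @export
print.topology_census <- function(x, ...) {
  cat("Topology census over", x$total, "gene trees\n")
  top <- utils::head(x$classes, 6)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %4d (%5.1f%%) %-16s %s\n", top$count[i],
                100 * top$fraction[i], top$model[i], top$class[i]))
  cat("Plurality class model:", x$verdict, "\n")
  invisible(x)
}

#' Build anchor gene trees from a simulated complex
#'
#' For every gene family with the full 1:2:4 copy complement, builds a
#' neighbor-joining tree on Jukes-Cantor distances from the family's CDS
#' (the simulator emits gap-free homologs of equal length, so the raw
#' CDS matrix is already a valid codon alignment) and roots it on the
#' outgroup copy.
#'
#' @param sim a `polyploid_sim`.
#' @return list of rooted `phylo` trees, tip labels are genome copies.
#' @export
anchor_gene_trees <- function(sim) {
  g <- sim$genes[!sim$genes$single_copy, ]
  fams <- split(g, g$family)
  fams <- Filter(function(f) nrow(f) == 7L, fams)
  lapply(fams, function(f) {
    aln <- stats::setNames(f$cds, f$leaf)
    if (length(unique(nchar(aln))) != 1L) {
      prot <- align_progressive(translate_cds(gsub("TAA|TAG|TGA", "NNN",
                                                   aln)))
      aln <- backtranslate(prot, as.list(aln))
    }
    root_on_outgroup(build_nj(aln), "out")
  })
}

#' Group anchor sets by homoeologous chromosome tuple
#'
#' Anchors sharing the identical full chromosome set (one chromosome per
#' genome copy) form a macro-synteny group; groups below `min_genes`
#' anchors are dropped. Concatenating the member gene alignments of one
#' group yields a macro-synteny tree.
#'
#' @param anchor_members data.frame with columns `anchor_id` and `chrom`
#'   (one row per anchor member gene), e.g. the `members` element of
#'   [extract_anchor_groups()].
#' @param min_genes minimum anchors per retained group.
#' @return data.frame with columns `chrom_set`, `n_anchors` and list
#'   column `anchor_ids`.
#' @export
macro_synteny_groups <- function(anchor_members, min_genes = 1L) {
  tuples <- vapply(split(anchor_members$chrom, anchor_members$anchor_id),
                   function(ch) paste(sort(unique(ch)), collapse = "|"),
                   character(1))
  sp <- split(names(tuples), tuples)
  sp <- sp[vapply(sp, length, integer(1)) >= min_genes]
  if (!length(sp))
    return(data.frame(chrom_set = character(0), n_anchors = integer(0)))
  out <- data.frame(chrom_set = names(sp),
                    n_anchors = vapply(sp, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$anchor_ids <- unname(sp)
  rownames(out) <- NULL
  out[order(-out$n_anchors), ]
}
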