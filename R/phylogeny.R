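#' Fixed four-species phylogeny context
#'
#' The analyses in this package operate on a fixed, rooted four-taxon topology
#' with one outgroup: `(((Dmel,Dsim),Dyak),Dana)`. Each terminal branch has a
#' known divergence age (million years to the last common ancestor with the
#' reference lineage): 5 My for the Dmel and Dsim branches, 13 My for Dyak and
#' 44 My for the outgroup Dana. All transition classification and conservation
#' tiers are defined relative to this context.
#'
#' @param species Character vector of exactly four species labels, ordered from
#'   the reference species to the outgroup.
#' @param ages Named numeric vector of divergence ages (My), one per species.
#'   Ages must be non-decreasing toward the outgroup and the outgroup age must
#'   strictly exceed the ingroup ages.
#'
#' @return An object of class `phylo_context`: a list with elements
#'   `species` (ordered labels), `ages` (named ages), `outgroup` (last label),
#'   `ingroup` (first three labels) and `newick` (the rooted topology string).
#' @examples
#' phy <- phylo_context()
#' phy$ages
#' @export
phylo_context <- function(species = c("Dmel", "Dsim", "Dyak", "Dana"),
                          ages = c(Dmel = 5, Dsim = 5, Dyak = 13, Dana = 44)) {
  if (length(species) != 4L || anyDuplicated(species))
    stop("exactly four distinct species labels are required", call. = FALSE)
  if (!all(species %in% names(ages)))
    stop("every species needs a divergence age", call. = FALSE)
  ages <- ages[species]
  if (!(ages[[3L]] > ages[[1L]] && ages[[4L]] > ages[[3L]]))
    stop("divergence ages must increase toward the outgroup", call. = FALSE)
  structure(
    list(
      species  = species,
      ages     = ages,
      ingroup  = species[1:3],
      outgroup = species[4L],
      newick   = sprintf("(((%s,%s),%s),%s);",
                         species[1L], species[2L], species[3L], species[4L])
    ),
    class = "phylo_context"
  )
}

#' @export
print.phylo_context <- function(x, ...) {
  cat("Four-species phylogeny context\n")
  cat("  topology :", x$newick, "\n")
  cat("  ages (My):", paste(sprintf("%s=%g", x$species, x$ages), collapse = ", "),
      "\n")
  invisible(x)
}

# internal: validate a species label vector against the context
.check_species <- function(labels, phylo) {
  bad <- setdiff(unique(labels), phylo$species)
  if (length(bad))
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
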