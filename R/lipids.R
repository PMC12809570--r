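#' @useDynLib memiso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Atom-name generation follows CHARMM36 lipid conventions: sn-1 tail carbons
# C31..C3n with hydrogens HnX/HnY, sn-2 carbons C21..C2n with HnR/HnS, and
# cardiolipin acyl chains CA/CB/CC/CD with HAnR-style hydrogens.  Vinyl
# (double-bond) carbons carry a single hydrogen; all other tail carbons two.

#' Describe one acyl tail
#'
#' Builds the atom-level description of a single acyl chain from a compact
#' descriptor such as \code{"16:1"}.  Carbon atom names are
#' \code{<carbon_prefix><i>} for i = 1 (carbonyl, glycerol-proximal) to
#' i = n (terminal methyl).  Each unsaturation position i denotes the
#' double bond C(i)=C(i+1); its dihedral is measured over
#' C(i-1), C(i), C(i+1), C(i+2).
#'
#' @param descriptor character like \code{"16:0"} or \code{"18:1"}; the number
#'   after the colon must equal \code{length(unsaturations)}.
#' @param carbon_prefix prefix for carbon atom names (e.g. \code{"C2"} for the
#'   sn-2 chain).
#' @param hydrogen_prefix prefix for hydrogen atom names (usually \code{"H"}).
#' @param hydrogen_suffixes two single-character suffixes distinguishing the
#'   geminal hydrogens (e.g. \code{c("R", "S")}).
#' @param unsaturations integer vector of double-bond positions, each strictly
#'   inside the chain (position p satisfies 2 <= p <= n - 2 so that the
#'   four dihedral atoms exist).
#' @return An object of class \code{"tail_spec"}.
#' @export
tail_spec <- function(descriptor, carbon_prefix, hydrogen_prefix = "H",
                      hydrogen_suffixes = c("R", "S"),
                      unsaturations = integer(0)) {
  parts <- strsplit(descriptor, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("tail descriptor must look like '16:1', got: ", descriptor)
  n <- as.integer(parts[1])
  n_unsat <- as.integer(parts[2])
  unsaturations <- as.integer(unsaturations)
  if (length(unsaturations) != n_unsat)
    stop("tail descriptor ", descriptor, " promises ", n_unsat,
         " unsaturation(s) but ", length(unsaturations), " position(s) given")
  if (length(hydrogen_suffixes) != 2L)
    stop("exactly two hydrogen suffixes are required")
  if (any(unsaturations < 2L | unsaturations > n - 2L))
    stop("unsaturation positions must lie strictly inside the chain ",
         "(2 <= p <= n-2); got ", paste(unsaturations, collapse = ", "),
         " for n = ", n)

  carbons <- paste0(carbon_prefix, seq_len(n))
  vinyl <- sort(unique(c(unsaturations, unsaturations + 1L)))
  hydrogens <- lapply(seq_len(n), function(i) {
    if (i %in% vinyl) {
      paste0(hydrogen_prefix, i, hydrogen_suffixes[1])
    } else {
      paste0(hydrogen_prefix, i, hydrogen_suffixes)
    }
  })
  unsat <- lapply(unsaturations, function(p) {
    list(position = p,
         dihedral_atoms = carbons[c(p - 1L, p, p + 1L, p + 2L)])
  })
  structure(list(descriptor = descriptor,
                 n_carbons = n,
                 carbons = carbons,
                 hydrogens = hydrogens,
                 unsaturations = unsat,
                 carbonyl = carbons[1],
                 terminal = carbons[n]),
            class = "tail_spec")
}

#' Describe one lipid species
#'
#' @param residue_name residue code as used in structure files (e.g.
#'   \code{"PYPE"}).
#' @param headgroup one of \code{"PE"}, \code{"PG"}, \code{"CL"}.
#' @param phosphate_atoms atom names of the phosphorus atoms and their bonded
#'   oxygens; for cardiolipin both phosphate groups contribute.
#' @param tails list of \code{\link{tail_spec}} objects, sn-1 first.
#' @return An object of class \code{"lipid_spec"}.
#' @export
lipid_spec <- function(residue_name, headgroup, phosphate_atoms, tails) {
  headgroup <- match.arg(headgroup, c("PE", "PG", "CL"))
  if (length(tails) < 1L) stop("a lipid needs at least one tail")
  if (!all(vapply(tails, inherits, logical(1), "tail_spec")))
    stop("tails must be tail_spec objects")
  if (length(phosphate_atoms) < 1L) stop("phosphate_atoms must be non-empty")
  nm <- c(phosphate_atoms,
          unlist(lapply(tails, function(t) c(t$carbons, unlist(t$hydrogens)))))
  if (anyDuplicated(nm))
    stop("duplicate atom names within lipid ", residue_name, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(residue_name = residue_name,
                 headgroup_class = headgroup,
                 phosphate_atoms = phosphate_atoms,
                 tails = tails),
            class = "lipid_spec")
}

#' @export
print.lipid_spec <- function(x, ...) {
  cat(sprintf("<lipid_spec> %s (%s): %s; %d phosphate atoms, %d atoms total\n",
              x$residue_name, x$headgroup_class,
              paste(vapply(x$tails, `[[`, character(1), "descriptor"),
                    collapse = "/"),
              length(x$phosphate_atoms), n_atoms_per_lipid(x)))
  invisible(x)
}

#' Number of atoms in one instance of a lipid
#' @param spec a \code{lipid_spec}.
#' @return integer atom count.
#' @export
n_atoms_per_lipid <- function(spec) {
  length(spec$phosphate_atoms) +
    sum(vapply(spec$tails, function(t) {
      t$n_carbons + length(unlist(t$hydrogens))
    }, numeric(1)))
}

#' Read a lipid-definition table
#'
#' The table is a plain-text YAML config, one record per residue name, and is
#' the single source of atom-name roles (phosphates, tail carbons, hydrogens,
#' double-bond positions).  The copy shipped with the package covers the six
#' species of the Pseudomonas putida inner-membrane model and can be copied
#' and edited to add species.
#'
#' @param path path to a YAML file; defaults to the shipped table.
#' @return Named list of \code{\link{lipid_spec}} objects.
#' @export
read_lipid_definitions <- function(path = system.file("extdata",
                                                      "lipid_definitions.yaml",
                                                      package = "memiso")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    tails <- lapply(r$tails, function(t) {
      tail_spec(descriptor = t$descriptor,
                carbon_prefix = t$carbon_prefix,
                hydrogen_prefix = t$hydrogen_prefix,
                hydrogen_suffixes = unlist(t$hydrogen_suffixes),
                unsaturations = unlist(t$unsaturations) %||% integer(0))
    })
    lipid_spec(nm, r$headgroup, unlist(r$phosphate_atoms), tails)
  })
  names(out) <- names(raw)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.memiso_env <- new.env(parent = emptyenv())

#' Default lipid definitions (shipped table, cached)
#' @return Named list of \code{lipid_spec} objects.
#' @export
lipid_definitions <- function() {
  if (is.null(.memiso_env$defs)) .memiso_env$defs <- read_lipid_definitions()
  .memiso_env$defs
}

#' Membrane composition
#'
#' Pairs lipid species with per-leaflet copy numbers.
#'
#' @param specs named list of \code{\link{lipid_spec}} objects.
#' @param counts named integer vector of per-leaflet counts; names must match
#'   \code{specs}.
#' @return An object of class \code{"membrane_composition"}.
#' @export
membrane_composition <- function(specs, counts) {
  if (is.null(names(counts)) || !all(names(counts) %in% names(specs)))
    stop("counts must be named by residue name with matching specs")
  counts <- counts[counts > 0]
  if (any(counts != as.integer(counts)) || any(counts < 0))
    stop("counts must be nonnegative integers")
  structure(list(specs = specs[names(counts)],
                 counts = stats::setNames(as.integer(counts), names(counts))),
            class = "membrane_composition")
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("<membrane_composition>", sum(x$counts), "lipids per leaflet\n")
  for (i in seq_along(x$counts)) {
    s <- x$specs[[i]]
    cat(sprintf("  %-6s %2d  %s (%s)\n", s$residue_name, x$counts[i],
                paste(vapply(s$tails, `[[`, character(1), "descriptor"),
                      collapse = "/"), s$headgroup_class))
  }
  invisible(x)
}

#' Per-leaflet composition of the P. putida inner-membrane model
#'
#' The default model is a 100-lipid patch (50 per leaflet) of five
#' glycerophospholipids and cardiolipin: PYPE 10, POPE 7, YOPE 14, PYPG 11,
#' POPG 6, PVCL2 2 per leaflet.  All unsaturations are Delta-9.
#'
#' @param definitions lipid-definition list, defaults to the shipped table.
#' @return A \code{\link{membrane_composition}} with 50 lipids per leaflet.
#' @export
#' @examples
#' comp <- default_composition()
#' sum(comp$counts)  # 50 per leaflet
default_composition <- function(definitions = lipid_definitions()) {
  counts <- c(PYPE = 10L, POPE = 7L, YOPE = 14L,
              PYPG = 11L, POPG = 6L, PVCL2 = 2L)
  membrane_composition(definitions, counts)
}
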