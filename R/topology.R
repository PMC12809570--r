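# Topology resolution: atom roles, bond graph, unsaturation sites.
# Roles: "P" phosphorus, "OP" phosphate oxygen, "C" tail carbon,
# "H" tail hydrogen, "other" non-lipid.

# Per-lipid atom/role template derived from a lipid_spec.  Local bond graph
# uses reduced connectivity: P-O within each phosphate group, each tail
# carbonyl attached to the first phosphate atom, C(i)-C(i+1) along each chain,
# and C-H bonds.  This is all the bond information the isomerization operator
# needs (head connectivity only has to make the molecule one component).
lipid_template <- function(spec) {
  atom <- character(0); role <- character(0)
  tailv <- integer(0); pos <- integer(0); parent <- integer(0)
  db <- logical(0)
  bonds <- matrix(integer(0), ncol = 2)

  np <- length(spec$phosphate_atoms)
  is_p <- grepl("^P", spec$phosphate_atoms)
  atom <- c(atom, spec$phosphate_atoms)
  role <- c(role, ifelse(is_p, "P", "OP"))
  tailv <- c(tailv, rep(NA_integer_, np))
  pos <- c(pos, rep(NA_integer_, np))
  parent <- c(parent, rep(NA_integer_, np))
  db <- c(db, rep(FALSE, np))
  # bond each phosphate oxygen to the nearest preceding phosphorus
  last_p <- NA_integer_
  for (i in seq_len(np)) {
    if (is_p[i]) last_p <- i
    else if (!is.na(last_p)) bonds <- rbind(bonds, c(last_p, i))
  }

  sites <- list()
  for (ti in seq_along(spec$tails)) {
    t <- spec$tails[[ti]]
    vinyl <- integer(0)
    for (u in t$unsaturations) vinyl <- c(vinyl, u$position, u$position + 1L)
    c_idx <- integer(t$n_carbons)
    for (ci in seq_len(t$n_carbons)) {
      atom <- c(atom, t$carbons[ci]); role <- c(role, "C")
      tailv <- c(tailv, ti); pos <- c(pos, ci)
      parent <- c(parent, NA_integer_); db <- c(db, ci %in% vinyl)
      c_idx[ci] <- length(atom)
      hs <- t$hydrogens[[ci]]
      for (h in hs) {
        atom <- c(atom, h); role <- c(role, "H")
        tailv <- c(tailv, ti); pos <- c(pos, ci)
        parent <- c(parent, c_idx[ci]); db <- c(db, FALSE)
        bonds <- rbind(bonds, c(c_idx[ci], length(atom)))
      }
      if (ci > 1L) bonds <- rbind(bonds, c(c_idx[ci - 1L], c_idx[ci]))
    }
    bonds <- rbind(bonds, c(1L, c_idx[1]))  # tail anchored to head
    for (u in t$unsaturations) {
      p <- u$position
      sites[[length(sites) + 1L]] <-
        list(tail = ti, position = p,
             a = c_idx[c(p - 1L, p, p + 1L, p + 2L)],
             carbonyl = c_idx[1], terminal = c_idx[t$n_carbons])
    }
  }
  list(atoms = data.frame(atom = atom, role = role, tail = tailv, pos = pos,
                          parent = parent, db = db,
                          stringsAsFactors = FALSE),
       bonds = bonds, sites = sites)
}

.solvent_names <- c("SOL", "TIP3", "TIP3P", "WAT", "HOH", "SPC", "TIP4",
                    "POT", "CLA", "SOD", "NA", "CL", "K", "MG", "CAL", "ION")

#' Resolve atom roles for every residue of a raw topology
#'
#' Matches each residue's atoms against the lipid-definition table, assigning
#' roles (phosphate P/O, tail carbon, tail hydrogen), the intra-lipid bond
#' graph, and one unsaturation site per double bond per residue instance.
#' Residues with common solvent/ion names are tagged non-lipid; any other
#' residue name without a matching spec is an error.
#'
#' @param raw data.frame with columns \code{resid} (integer residue id),
#'   \code{resname}, \code{atom} (atom name), in file order.
#' @param specs named list of \code{\link{lipid_spec}} objects.
#' @return An object of class \code{"mem_topology"}: list with \code{atoms}
#'   (per-atom table with roles), \code{bonds} (2-column global index matrix),
#'   \code{sites} (one row per unsaturation site, class
#'   \code{"unsaturation_sites"}).
#' @export
annotate_topology <- function(raw, specs = lipid_definitions()) {
  stopifnot(all(c("resid", "resname", "atom") %in% names(raw)))
  n <- nrow(raw)
  atoms <- data.frame(index = seq_len(n), atom = raw$atom,
                      resid = raw$resid, resname = raw$resname,
                      role = "other", tail = NA_integer_, pos = NA_integer_,
                      parent = NA_integer_, db = FALSE, is_lipid = FALSE,
                      leaflet = NA_character_, stringsAsFactors = FALSE)
  bonds <- list(); sites <- list()
  templates <- list()
  for (rid in unique(raw$resid)) {
    rows <- which(raw$resid == rid)
    rn <- raw$resname[rows[1]]
    if (!rn %in% names(specs)) {
      if (toupper(rn) %in% .solvent_names) next
      stop("unknown lipid residue name: ", rn,
           " (no entry in the lipid-definition table)")
    }
    if (is.null(templates[[rn]])) templates[[rn]] <- lipid_template(specs[[rn]])
    tpl <- templates[[rn]]
    m <- match(tpl$atoms$atom, raw$atom[rows])
    if (anyNA(m)) {
      stop("residue ", rid, " (", rn, ") is missing role atom(s): ",
           paste(tpl$atoms$atom[is.na(m)], collapse = ", "))
    }
    g <- rows[m]  # global index per template row
    atoms$role[g] <- tpl$atoms$role
    atoms$tail[g] <- tpl$atoms$tail
    atoms$pos[g] <- tpl$atoms$pos
    atoms$parent[g] <- ifelse(is.na(tpl$atoms$parent), NA_integer_,
                              g[tpl$atoms$parent])
    atoms$db[g] <- tpl$atoms$db
    atoms$is_lipid[rows] <- TRUE
    if (nrow(tpl$bonds))
      bonds[[length(bonds) + 1L]] <-
        cbind(g[tpl$bonds[, 1]], g[tpl$bonds[, 2]])
    for (s in tpl$sites) {
      sites[[length(sites) + 1L]] <-
        data.frame(resid = rid, resname = rn, tail = s$tail,
                   position = s$position,
                   a1 = g[s$a[1]], a2 = g[s$a[2]], a3 = g[s$a[3]],
                   a4 = g[s$a[4]], carbonyl = g[s$carbonyl],
                   terminal = g[s$terminal], stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(resid = integer(0), resname = character(0), tail = integer(0),
               position = integer(0), a1 = integer(0), a2 = integer(0),
               a3 = integer(0), a4 = integer(0), carbonyl = integer(0),
               terminal = integer(0))
  class(sites) <- c("unsaturation_sites", "data.frame")
  structure(list(atoms = atoms,
                 bonds = if (length(bonds)) do.call(rbind, bonds) else
                   matrix(integer(0), ncol = 2),
                 sites = sites),
            class = "mem_topology")
}

#' @export
print.mem_topology <- function(x, ...) {
  nl <- length(unique(x$atoms$resid[x$atoms$is_lipid]))
  cat(sprintf("<mem_topology> %d atoms, %d lipid residues, %d unsaturation sites\n",
              nrow(x$atoms), nl, nrow(x$sites)))
  invisible(x)
}

# Raw topology (resid/resname/atom rows) for a composition instantiated over
# both leaflets; lipid instances of the upper leaflet come first.
instantiate_composition <- function(composition,
                                    leaflets = c("upper", "lower")) {
  rows <- list(); rid <- 0L
  leaf <- character(0)
  for (lf in leaflets) {
    for (i in seq_along(composition$counts)) {
      spec <- composition$specs[[i]]
      tpl_atoms <- lipid_template(spec)$atoms
      for (k in seq_len(composition$counts[i])) {
        rid <- rid + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(resid = rid, resname = spec$residue_name,
                     atom = tpl_atoms$atom, stringsAsFactors = FALSE)
        leaf <- c(leaf, lf)
      }
    }
  }
  list(raw = do.call(rbind, rows), leaflet_by_resid = leaf)
}
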