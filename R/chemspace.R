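#' @importFrom methods as is
#' @importFrom stats median sd quantile setNames rnorm runif kmeans
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# SMILES plumbing (OpenBabel via ChemmineOB)
# ---------------------------------------------------------------------------

.canon1 <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  out <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  if (is.na(out) || !nzchar(out)) return(NA_character_)
  smi <- sub("[\t ].*$", "", out)
  if (!nzchar(smi)) NA_character_ else smi
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the OpenBabel canonical form. Canonicalization is
#' idempotent: `canonical_smiles(canonical_smiles(s))` equals
#' `canonical_smiles(s)`. Unparseable strings yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES (`NA` where parsing failed).
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), .canon1, character(1), USE.NAMES = FALSE)
}

#' Average molecular weight from SMILES
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector of average molecular weights (g/mol), `NA` for
#'   unparseable input.
#' @export
molecular_weight <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    p <- tryCatch(
      ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", s, identity)),
      error = function(e) NULL
    )
    if (is.null(p) || !nrow(p)) NA_real_ else as.numeric(p$MW[1])
  }, numeric(1), USE.NAMES = FALSE)
}

.mol_table <- function(id, smiles, role,
                       core_id = NA_character_,
                       substituent_id = NA_character_,
                       reaction_id = NA_character_,
                       mw = NULL) {
  if (length(id) == 0L) {
    return(data.frame(id = character(0), smiles = character(0),
                      role = character(0), mw = numeric(0),
                      core_id = character(0), substituent_id = character(0),
                      reaction_id = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(mw)) mw <- molecular_weight(smiles)
  data.frame(
    id = as.character(id), smiles = as.character(smiles),
    role = as.character(role), mw = as.numeric(mw),
    core_id = core_id, substituent_id = substituent_id,
    reaction_id = reaction_id,
    stringsAsFactors = FALSE
  )
}

#' Load molecules from a SMILES file
#'
#' Reads a whitespace-separated `SMILES [id]` file (one record per line),
#' canonicalizes every record and computes molecular weights. Records that do
#' not parse are reported (with their line numbers) in the `"failures"`
#' attribute and via a message, not raised as errors. Missing ids are
#' auto-assigned from the file order.
#'
#' @param path path to the SMILES file.
#' @param role one of `"accessible"`, `"generated"`, `"substituent"`,
#'   `"solvent"`.
#' @return a molecule table: `data.frame` with columns `id`, `smiles`
#'   (canonical), `role`, `mw`, and provenance columns (`core_id`,
#'   `substituent_id`, `reaction_id`, `NA` for loaded molecules). Attribute
#'   `"failures"` is a data.frame of rejected lines.
#' @export
load_molecules <- function(path,
                           role = c("accessible", "generated",
                                    "substituent", "solvent")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  raw_smi <- vapply(toks, `[`, character(1), 1L)
  raw_id <- vapply(toks, function(x) if (length(x) >= 2) x[2] else NA_character_,
                   character(1))
  can <- canonical_smiles(raw_smi)
  bad <- is.na(can)
  failures <- data.frame(line = keep[bad], text = lines[keep][bad],
                         stringsAsFactors = FALSE)
  if (nrow(failures)) {
    message(nrow(failures), " unparseable record(s) at line(s): ",
            paste(failures$line, collapse = ", "))
  }
  can <- can[!bad]
  ids <- raw_id[!bad]
  auto <- is.na(ids)
  ids[auto] <- sprintf("%s_%03d", substr(role, 1, 3), which(auto))
  if (anyDuplicated(ids[!auto])) {
    stop("duplicate explicit ids in ", path, ": ",
         paste(unique(ids[!auto][duplicated(ids[!auto])]), collapse = ", "))
  }
  if (length(can) == 0L) stop("zero valid records in ", path)
  out <- .mol_table(ids, can, role)
  attr(out, "failures") <- failures
  out
}

#' Keep substituents below a molecular-weight limit
#'
#' Strict inequality: a molecule with `mw` exactly equal to `mw_limit` is
#' excluded. Input order is preserved; an empty result is allowed.
#'
#' @param mols molecule table (see [load_molecules()]).
#' @param mw_limit molecular-weight cutoff in g/mol (default 200).
#' @return the filtered molecule table.
#' @export
filter_substituents <- function(mols, mw_limit = 200) {
  stopifnot(is.data.frame(mols), !anyNA(mols$mw))
  mols[mols$mw < mw_limit, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Molecular graph + functional-group perception
# ---------------------------------------------------------------------------

# Parse a SMILES into a light heavy-atom graph: element labels plus a
# (from, to, order) bond table. Hydrogens are implicit; the SDF produced by
# OpenBabel is kekulized, so bond orders are 1/2/3.
.mol_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elem <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    matrix(integer(0), ncol = 3)
  } else {
    unname(cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3])))
  }
  list(elem = elem, bonds = bonds)
}

.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4)

.graph_stats <- function(g) {
  n <- length(g$elem)
  deg <- integer(n); bosum <- integer(n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 2]; o <- g$bonds[r, 3]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bosum[a] <- bosum[a] + o; bosum[b] <- bosum[b] + o
    }
  }
  val <- .DEFAULT_VALENCE[g$elem]
  val[is.na(val)] <- 0
  list(degree = deg, bond_order_sum = bosum,
       implicit_h = pmax(0L, as.integer(val) - bosum))
}

# Atoms lying on a cycle: endpoints of any non-bridge edge.
.ring_atoms <- function(g) {
  n <- length(g$elem)
  inring <- rep(FALSE, n)
  if (nrow(g$bonds) == 0L) return(inring)
  ig <- igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE],
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  br <- igraph::bridges(ig)
  ring_edges <- setdiff(seq_len(nrow(g$bonds)), as.integer(br))
  if (length(ring_edges)) {
    inring[unique(as.vector(g$bonds[ring_edges, 1:2]))] <- TRUE
  }
  inring
}

.adj <- function(g, i) {
  b <- g$bonds
  if (!nrow(b)) return(list(idx = integer(0), order = integer(0)))
  sel1 <- b[, 1] == i; sel2 <- b[, 2] == i
  list(idx = c(b[sel2, 1], b[sel1, 2]), order = c(b[sel2, 3], b[sel1, 3]))
}

# Carbonyl carbons: C with a double bond to a terminal O.
.carbonyl_carbons <- function(g) {
  which(vapply(seq_along(g$elem), function(i) {
    if (g$elem[i] != "C") return(FALSE)
    a <- .adj(g, i)
    any(g$elem[a$idx] == "O" & a$order == 2)
  }, logical(1)))
}

# Carboxylic acids: list of sites c(c = carbonyl C, oh = hydroxyl O).
.find_carboxyl <- function(g) {
  st <- .graph_stats(g)
  sites <- list()
  for (ci in .carbonyl_carbons(g)) {
    a <- .adj(g, ci)
    oh <- a$idx[g$elem[a$idx] == "O" & a$order == 1 &
                  st$degree[a$idx] == 1L]
    for (o in oh) sites[[length(sites) + 1L]] <- c(c = ci, oh = o)
  }
  sites
}

# Primary/secondary amines: non-ring N with >=1 implicit H, not adjacent to a
# carbonyl carbon (amide N excluded). Ring nitrogens are excluded altogether
# because the kekulized connection table cannot separate pyrrole-type NH
# (unreactive macrocycle nitrogen) from aliphatic ring amines.
.find_amine <- function(g) {
  st <- .graph_stats(g)
  ring <- .ring_atoms(g)
  carbonyl <- .carbonyl_carbons(g)
  sites <- list()
  for (i in which(g$elem == "N")) {
    if (ring[i] || st$implicit_h[i] < 1L) next
    a <- .adj(g, i)
    if (any(a$order > 1)) next
    if (any(a$idx %in% carbonyl)) next
    sites[[length(sites) + 1L]] <- c(n = i)
  }
  sites
}

# Alcohols/phenols: terminal O single-bonded to a non-carbonyl carbon.
.find_hydroxyl <- function(g) {
  st <- .graph_stats(g)
  carbonyl <- .carbonyl_carbons(g)
  sites <- list()
  for (i in which(g$elem == "O")) {
    if (st$degree[i] != 1L) next
    a <- .adj(g, i)
    if (a$order[1] != 1L) next
    cnb <- a$idx[1]
    if (g$elem[cnb] != "C" || cnb %in% carbonyl) next
    sites[[length(sites) + 1L]] <- c(o = i, c = cnb)
  }
  sites
}

# Alkyl halides: terminal Cl/Br/I on a non-carbonyl, non-aromatic-typed sp3
# carbon (no double bonds at the carbon).
.find_halide <- function(g) {
  st <- .graph_stats(g)
  sites <- list()
  for (i in which(g$elem %in% c("Cl", "Br", "I"))) {
    if (st$degree[i] != 1L) next
    a <- .adj(g, i)
    cnb <- a$idx[1]
    if (g$elem[cnb] != "C") next
    ca <- .adj(g, cnb)
    if (any(ca$order > 1)) next
    sites[[length(sites) + 1L]] <- c(x = i, c = cnb)
  }
  sites
}

#' Reaction templates for one-step derivatization
#'
#' Three one-step couplings between a core and a small substituent, each with
#' its required functional-group handles:
#' \describe{
#'   \item{amide}{core carboxylic acid + substituent primary/secondary amine
#'     -> amide (+ water); the acid hydroxyl leaves.}
#'   \item{ester}{core carboxylic acid + substituent alcohol/phenol -> ester
#'     (+ water).}
#'   \item{ether}{Williamson coupling, enumerated in both orientations: core
#'     hydroxyl + substituent alkyl halide, and core alkyl halide +
#'     substituent hydroxyl; the halide leaves.}
#' }
#' A (core, substituent) pair lacking either handle yields no product.
#'
#' @param ids subset of `c("amide", "ester", "ether")`.
#' @return list of template objects (id, orientation, site finders, edit rule).
#' @export
reaction_templates <- function(ids = c("amide", "ester", "ether")) {
  ids <- match.arg(ids, several.ok = TRUE)
  all <- list(
    list(id = "amide", orientation = "fwd",
         core_sites = .find_carboxyl, sub_sites = .find_amine,
         edit = function(cs, ss) list(del_core = unname(cs["oh"]),
                                      del_sub = integer(0),
                                      bond = c(unname(cs["c"]), unname(ss["n"])))),
    list(id = "ester", orientation = "fwd",
         core_sites = .find_carboxyl, sub_sites = .find_hydroxyl,
         edit = function(cs, ss) list(del_core = unname(cs["oh"]),
                                      del_sub = integer(0),
                                      bond = c(unname(cs["c"]), unname(ss["o"])))),
    list(id = "ether", orientation = "fwd",
         core_sites = .find_hydroxyl, sub_sites = .find_halide,
         edit = function(cs, ss) list(del_core = integer(0),
                                      del_sub = unname(ss["x"]),
                                      bond = c(unname(cs["o"]), unname(ss["c"])))),
    list(id = "ether", orientation = "rev",
         core_sites = .find_halide, sub_sites = .find_hydroxyl,
         edit = function(cs, ss) list(del_core = unname(cs["x"]),
                                      del_sub = integer(0),
                                      bond = c(unname(cs["c"]), unname(ss["o"]))))
  )
  Filter(function(t) t$id %in% ids, all)
}

# Combine a core graph with one substituent copy per edit; apply deletions and
# new single bonds; emit a V2000 molfile and return the canonical SMILES.
.assemble_product <- function(core, sub, edits) {
  elem <- core$elem
  bonds <- core$bonds
  new_bonds <- NULL
  del <- integer(0)
  for (e in edits) {
    off <- length(elem)
    elem <- c(elem, sub$elem)
    if (nrow(sub$bonds)) {
      sb <- sub$bonds
      sb[, 1:2] <- sb[, 1:2] + off
      bonds <- rbind(bonds, sb)
    }
    del <- c(del, e$del_core, e$del_sub + off)
    new_bonds <- rbind(new_bonds, c(e$bond[1], e$bond[2] + off, 1L))
  }
  bonds <- rbind(bonds, new_bonds)
  keep <- setdiff(seq_along(elem), del)
  remap <- integer(length(elem)); remap[keep] <- seq_along(keep)
  elem <- elem[keep]
  if (nrow(bonds)) {
    ok <- !(bonds[, 1] %in% del) & !(bonds[, 2] %in% del)
    bonds <- bonds[ok, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
  }
  sdf <- c(
    "product", "  solucover", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(elem), nrow(bonds)),
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            elem),
    if (nrow(bonds)) sprintf("%3d%3d%3d  0  0  0  0",
                             bonds[, 1], bonds[, 2], bonds[, 3]),
    "M  END", "$$$$"
  )
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN",
                              source = paste0(paste(sdf, collapse = "\n"), "\n")),
    error = function(e) ""
  )
  out <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  if (is.na(out) || !nzchar(out)) return(NA_character_)
  smi <- sub("[\t ].*$", "", out)
  if (!nzchar(smi)) NA_character_ else smi
}

#' Enumerate one-step products of cores and substituents
#'
#' Applies each reaction template to every (core, substituent) pair. In
#' `all_sites` mode the coupling is performed simultaneously at every matching
#' site of the core with the same substituent (full conversion, the usual
#' outcome for symmetric tetra-arm porphyrin cores); in `single_site` mode one
#' product is generated per distinct core site. Products are canonicalized and
#' deduplicated by canonical SMILES; provenance (`core_id`, `substituent_id`,
#' `reaction_id`) records the first triple that produced each structure.
#' Products that fail OpenBabel sanitization are dropped with a message, never
#' raised.
#'
#' @param cores,substituents molecule tables (see [load_molecules()]).
#' @param templates list from [reaction_templates()].
#' @param site_mode `"all_sites"` (default) or `"single_site"`.
#' @return molecule table of unique products with `role = "generated"`.
#' @export
enumerate_products <- function(cores, substituents,
                               templates = reaction_templates(),
                               site_mode = c("all_sites", "single_site")) {
  site_mode <- match.arg(site_mode)
  core_graphs <- lapply(cores$smiles, .mol_graph)
  sub_graphs <- lapply(substituents$smiles, .mol_graph)
  rows <- list()
  n_dropped <- 0L
  for (tpl in templates) {
    core_site_list <- lapply(core_graphs, tpl$core_sites)
    sub_site_list <- lapply(sub_graphs, tpl$sub_sites)
    for (ci in seq_along(core_graphs)) {
      csites <- core_site_list[[ci]]
      if (!length(csites)) next
      for (si in seq_along(sub_graphs)) {
        ssites <- sub_site_list[[si]]
        if (!length(ssites)) next
        for (ss in ssites) {
          edit_sets <- if (site_mode == "all_sites") {
            list(lapply(csites, function(cs) tpl$edit(cs, ss)))
          } else {
            lapply(csites, function(cs) list(tpl$edit(cs, ss)))
          }
          for (edits in edit_sets) {
            smi <- .assemble_product(core_graphs[[ci]], sub_graphs[[si]], edits)
            if (is.na(smi)) { n_dropped <- n_dropped + 1L; next }
            rows[[length(rows) + 1L]] <- data.frame(
              smiles = smi, core_id = cores$id[ci],
              substituent_id = substituents$id[si], reaction_id = tpl$id,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (n_dropped) message(n_dropped, " product(s) failed sanitization; dropped")
  if (!length(rows)) {
    return(.mol_table(character(0), character(0), character(0),
                      mw = numeric(0)))
  }
  prod <- do.call(rbind, rows)
  prod <- prod[!duplicated(prod$smiles), , drop = FALSE]
  out <- .mol_table(sprintf("gen_%04d", seq_len(nrow(prod))), prod$smiles,
                    "generated", core_id = prod$core_id,
                    substituent_id = prod$substituent_id,
                    reaction_id = prod$reaction_id)
  rownames(out) <- NULL
  out
}
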