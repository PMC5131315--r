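#' Chemical group tags
#'
#' The atom groups tracked by the analyses: phosphate phosphorus, choline
#' nitrogen, the two carbonyl oxygens (sn-1 / sn-2 ester), the PS carboxylate
#' oxygens, water oxygen, calcium, chloride, and a catch-all `OTHER`.
#'
#' @export
GROUP_TAGS <- c(
  "PHOS_P", "CHOL_N", "CARBONYL_O_SN1", "CARBONYL_O_SN2",
  "COO_PS", "WATER_O", "CA", "CL", "OTHER"
)

#' Construct a topology
#'
#' A topology is a data frame with one row per atom: atom name, residue name,
#' 1-based residue index, element, group tag, charge (e) and mass (amu).
#' Residue indices must be non-decreasing so that atoms of one molecule are
#' contiguous.
#'
#' @param atom character, atom names
#' @param resname character, residue names
#' @param resid integer, residue indices (>= 1, non-decreasing)
#' @param element character, element symbols (guessed from the atom name if
#'   omitted)
#' @param group group tags, one of [GROUP_TAGS] (default `"OTHER"`)
#' @param charge numeric, charges in e (default 0)
#' @param mass numeric, masses in amu (default 1)
#' @return an object of class `topology` (a data frame)
#' @export
topology <- function(atom, resname, resid, element = NULL,
                     group = "OTHER", charge = 0, mass = 1) {
  n <- length(atom)
  if (length(resname) == 1 && n > 1) resname <- rep(resname, n)
  stopifnot(length(resname) == n, length(resid) == n)
  resid <- as.integer(resid)
  if (n > 0 && any(resid < 1L)) stop("residue indices must be >= 1")
  if (n > 1 && any(diff(resid) < 0L))
    stop("residue indices must be non-decreasing within the topology")
  if (is.null(element)) element <- guess_element(atom)
  group <- match_group(group, n)
  top <- data.frame(
    atom = as.character(atom), resname = as.character(resname),
    resid = resid, element = as.character(element), group = group,
    charge = rep_len(as.numeric(charge), n), mass = rep_len(as.numeric(mass), n),
    stringsAsFactors = FALSE
  )
  class(top) <- c("topology", "data.frame")
  top
}

match_group <- function(group, n) {
  group <- rep_len(as.character(group), n)
  bad <- setdiff(unique(group), GROUP_TAGS)
  if (length(bad) > 0)
    stop("unknown group tag(s): ", paste(bad, collapse = ", "))
  factor(group, levels = GROUP_TAGS)
}

guess_element <- function(atom) {
  # first alphabetic character; two-letter symbols recognised for the ions
  up <- toupper(atom)
  el <- substr(gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", up)), 1, 1)
  el[grepl("^CA", up)] <- "Ca"
  el[grepl("^CL", up)] <- "Cl"
  el
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues\n", nrow(x),
              length(unique(x$resid))))
  tab <- table(x$group)
  tab <- tab[tab > 0]
  if (length(tab) > 0)
    cat("  group counts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Build a group map
#'
#' A group map sends (residue name, atom name) pairs to group tags. Pairs not
#' present in the map default to `OTHER`, so the mapping is total over any
#' topology.
#'
#' @param entries a data frame with columns `resname`, `atom`, `group`, or a
#'   named list of lists `resname -> atom -> group`
#' @return an object of class `group_map`
#' @seealso [default_group_map()], [read_group_map()]
#' @export
group_map <- function(entries) {
  if (is.data.frame(entries)) {
    df <- entries
  } else {
    rows <- list()
    for (rn in names(entries)) {
      atoms <- entries[[rn]]
      rows[[rn]] <- data.frame(resname = rn, atom = names(atoms),
                               group = unlist(atoms, use.names = FALSE),
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(resname = character(), atom = character(),
                                      group = character())
  }
  stopifnot(all(c("resname", "atom", "group") %in% names(df)))
  bad <- setdiff(unique(df$group), GROUP_TAGS)
  if (length(bad) > 0)
    stop("unknown group tag(s) in map: ", paste(bad, collapse = ", "))
  rownames(df) <- NULL
  structure(df[c("resname", "atom", "group")], class = c("group_map", "data.frame"))
}

#' Default group map for Berger-style POPC/POPS/SPC atom naming
#'
#' The shipped template tags the phosphate phosphorus (`P` / `P8`), choline
#' nitrogen (`N` / `N4`), the sn-1 and sn-2 ester carbonyl oxygens
#' (`O16`/`O33` in the Berger united-atom numbering, plus generic `OA`/`OB`
#' aliases used by the synthetic generator), the two PS carboxylate oxygens,
#' water oxygen (`OW`), and the ions.
#'
#' @return a [group_map()]
#' @export
default_group_map <- function() {
  group_map(data.frame(
    resname = c(rep("POPC", 8), rep("POPS", 10), "SOL", "CA", "CAL", "CL", "CLA"),
    atom = c("P", "P8", "N", "N4", "O16", "OA", "O33", "OB",
             "P", "P8", "N", "N4", "O16", "OA", "O33", "OB", "OC1", "OC2",
             "OW", "CA", "CA", "CL", "CL"),
    group = c("PHOS_P", "PHOS_P", "CHOL_N", "CHOL_N",
              "CARBONYL_O_SN1", "CARBONYL_O_SN1", "CARBONYL_O_SN2", "CARBONYL_O_SN2",
              "PHOS_P", "PHOS_P", "CHOL_N", "CHOL_N",
              "CARBONYL_O_SN1", "CARBONYL_O_SN1", "CARBONYL_O_SN2", "CARBONYL_O_SN2",
              "COO_PS", "COO_PS",
              "WATER_O", "CA", "CA", "CL", "CL"),
    stringsAsFactors = FALSE
  ))
}

#' Read a group map from a YAML config
#'
#' Layout: top-level keys are residue names, values are `atom: GROUP` pairs.
#'
#' @param path file path
#' @return a [group_map()]
#' @export
read_group_map <- function(path) {
  group_map(yaml::read_yaml(path))
}

#' Write a group map to a YAML config
#' @param map a [group_map()]
#' @param path file path
#' @export
write_group_map <- function(map, path) {
  out <- split(stats::setNames(as.list(map$group), map$atom), map$resname)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Apply a group map to a topology
#'
#' Every atom receives exactly one tag; (residue, atom) pairs absent from the
#' map fall back to `OTHER`, with a warning for each residue name that has no
#' entry in the map at all.
#'
#' @param top a [topology()]
#' @param map a [group_map()]
#' @param quiet suppress the unmapped-residue warning
#' @return the topology with groups assigned; the per-tag counts are attached
#'   as attribute `"tag_counts"`
#' @export
apply_group_map <- function(top, map, quiet = FALSE) {
  stopifnot(inherits(top, "topology"), inherits(map, "group_map"))
  key <- paste(top$resname, top$atom, sep = "\r")
  mkey <- paste(map$resname, map$atom, sep = "\r")
  idx <- match(key, mkey)
  tags <- ifelse(is.na(idx), "OTHER", as.character(map$group[idx]))
  unmapped_res <- setdiff(unique(top$resname), unique(map$resname))
  if (length(unmapped_res) > 0 && !quiet)
    warning("residue name(s) not in group map, tagged OTHER: ",
            paste(unmapped_res, collapse = ", "))
  top$group <- factor(tags, levels = GROUP_TAGS)
  attr(top, "tag_counts") <- table(top$group)
  top
}

#' Select atom indices by group tag and residue name
#'
#' @param top a [topology()]
#' @param tags one or more of [GROUP_TAGS]; must be non-empty
#' @param resname optional residue-name filter
#' @return sorted unique integer atom indices
#' @export
select_atoms <- function(top, tags, resname = NULL) {
  if (length(tags) == 0) stop("tag set must be non-empty")
  bad <- setdiff(tags, GROUP_TAGS)
  if (length(bad) > 0) stop("unknown tag(s): ", paste(bad, collapse = ", "))
  keep <- top$group %in% tags
  if (!is.null(resname)) keep <- keep & top$resname %in% resname
  sort(unique(which(keep)))
}

#' Group atom indices into chemical group instances
#'
#' Returns one integer index vector per group instance: multi-atom groups (the
#' two PS carboxylate oxygens; optionally the two carbonyl oxygens) are held
#' together so that downstream counting treats them as one site.
#'
#' @param top a [topology()]
#' @param tags tags forming one group instance per residue
#' @param resname optional residue filter
#' @return named list of integer vectors (names are residue indices)
#' @export
group_instances <- function(top, tags, resname = NULL) {
  idx <- select_atoms(top, tags, resname)
  if (length(idx) == 0) return(list())
  split(idx, top$resid[idx])
}
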