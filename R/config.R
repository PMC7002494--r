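#' Pipeline configuration
#'
#' All numeric thresholds used anywhere in the pipeline live in a single
#' configuration object; downstream code never hard-codes a cutoff. The
#' defaults implement the published interface-clustering protocol:
#' two units interact iff they have >= `min_cbeta_pairs` C-beta pairs within
#' `cbeta_cutoff` and >= 1 atomic contact within `atom_cutoff`, or >=
#' `min_atom_contacts` atomic contacts within `atom_cutoff`; interfaces are
#' clustered while the average Q score between clusters stays >= `q_cluster`.
#'
#' @param cbeta_cutoff C-beta--C-beta distance cutoff, Angstrom.
#' @param atom_cutoff heavy-atom contact distance cutoff, Angstrom.
#' @param min_cbeta_pairs minimum number of C-beta pairs for the first
#'   clause of the interaction rule.
#' @param min_atom_contacts minimum number of atomic contacts for the
#'   second clause of the interaction rule.
#' @param ligand_cutoff domain--ligand atomic contact cutoff, Angstrom.
#' @param min_bsa_chain minimum buried surface area (A^2) for a chain-level
#'   interface to enter clustering.
#' @param min_bsa_domain minimum buried surface area (A^2) for a
#'   domain-level interface to enter clustering.
#' @param q_cluster average-linkage merge threshold on the Q score.
#' @param q_high Q threshold above which two interfaces are considered
#'   "highly similar" (assembly containment, crystal-form merging).
#' @param cell_tol relative tolerance on unit-cell parameters when deciding
#'   whether two entries share a crystal form (0.01 = 1 percent).
#' @param cf_merge_fraction fraction of shared highly-similar interfaces
#'   required to merge two crystal forms (two thirds).
#' @param hmm_cov_min minimum HMM coverage of the shorter domain for an
#'   HMM-position correspondence to be usable.
#' @param peptide_max_len chains shorter than this many residues are
#'   peptides (exclusive bound; default 30).
#' @param peptide_assign_frac a peptide contacting several chains is
#'   assigned to one interface iff that interface holds at least this
#'   fraction of its atomic contacts.
#' @param pep_min_nhmm minimum number of shared HMM contact sites for
#'   merging two peptide-interface clusters.
#' @param pep_max_rmsd maximum peptide RMSD (A) for merging two
#'   peptide-interface clusters.
#' @param min_pep_overlap minimum residue overlap of an ungapped peptide
#'   alignment used in the peptide-RMSD scan.
#' @param ligand_site_jaccard Jaccard threshold on shared HMM contact
#'   positions for merging ligand-site clusters.
#' @param prune_radius bounding-box inflation (A) used when pruning
#'   placement pairs before contact detection; must be >= `cbeta_cutoff`.
#' @param sasa_probe solvent probe radius, Angstrom.
#' @param sasa_points sphere sample points per atom for the
#'   Shrake-Rupley surface computation.
#'
#' @return An object of class `xc_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$cbeta_cutoff
pipeline_config <- function(cbeta_cutoff = 12,
                            atom_cutoff = 5,
                            min_cbeta_pairs = 10,
                            min_atom_contacts = 5,
                            ligand_cutoff = 4.5,
                            min_bsa_chain = 100,
                            min_bsa_domain = 150,
                            q_cluster = 0.30,
                            q_high = 0.85,
                            cell_tol = 0.01,
                            cf_merge_fraction = 2 / 3,
                            hmm_cov_min = 0.80,
                            peptide_max_len = 30,
                            peptide_assign_frac = 0.75,
                            pep_min_nhmm = 3,
                            pep_max_rmsd = 10,
                            min_pep_overlap = 3,
                            ligand_site_jaccard = 0.5,
                            prune_radius = cbeta_cutoff + 5,
                            sasa_probe = 1.44,
                            sasa_points = 960) {
  cfg <- list(
    cbeta_cutoff = cbeta_cutoff, atom_cutoff = atom_cutoff,
    min_cbeta_pairs = min_cbeta_pairs, min_atom_contacts = min_atom_contacts,
    ligand_cutoff = ligand_cutoff, min_bsa_chain = min_bsa_chain,
    min_bsa_domain = min_bsa_domain, q_cluster = q_cluster, q_high = q_high,
    cell_tol = cell_tol, cf_merge_fraction = cf_merge_fraction,
    hmm_cov_min = hmm_cov_min, peptide_max_len = peptide_max_len,
    peptide_assign_frac = peptide_assign_frac, pep_min_nhmm = pep_min_nhmm,
    pep_max_rmsd = pep_max_rmsd, min_pep_overlap = min_pep_overlap,
    ligand_site_jaccard = ligand_site_jaccard, prune_radius = prune_radius,
    sasa_probe = sasa_probe, sasa_points = sasa_points
  )
  stopifnot(
    all(vapply(cfg, is.numeric, logical(1L))),
    cbeta_cutoff > 0, atom_cutoff > 0, ligand_cutoff > 0,
    min_cbeta_pairs >= 1, min_atom_contacts >= 1,
    q_cluster > 0, q_cluster <= 1, q_high > 0, q_high <= 1,
    cell_tol > 0, cf_merge_fraction > 0, cf_merge_fraction <= 1,
    hmm_cov_min > 0, hmm_cov_min <= 1,
    peptide_assign_frac > 0, peptide_assign_frac <= 1,
    ligand_site_jaccard > 0, ligand_site_jaccard <= 1,
    prune_radius >= cbeta_cutoff,
    sasa_probe > 0, sasa_points >= 12
  )
  class(cfg) <- "xc_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields present in the file override the defaults of [pipeline_config()];
#' unknown fields are an error. `overrides` (e.g. parsed CLI flags) take
#' precedence over file values.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file values.
#' @return An `xc_config` object.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.xc_config <- function(x, ...) {
  cat("<xc_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
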