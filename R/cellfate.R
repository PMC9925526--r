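# The cell-fate decision HPN: ionizing radiation induces DNA double-strand
# breaks (DSBs); the nuclear p53 signalling network (DSB repair, ATM
# activation, the p53-Mdm2 and p53-Wip1-ATM negative feedback loops, and
# p53-driven transcription) is stochastic; the cytoplasmic apoptosis
# induction pathway (caspase cascade, Bax/Bcl2, XIAP/SMAC, apoptosome) is
# continuous; stochastic mRNA transport transitions bridge the two, with the
# molecules-to-nM trans ratio as post-arc weight.

#' Poisson DSB input for a given radiation dose
#'
#' The number of radiation-induced double-strand breaks is drawn from a
#' Poisson distribution with mean `35 * ir_dose` (DSBs per Gray), and split
#' 70% simple / 30% complex: `sdsb = round(0.7 * total)`,
#' `cdsb = total - sdsb`.
#'
#' @param ir_dose Radiation dose in Gray (>= 0).
#' @return A `dsb_input` record with fields `ir_dose`, `total_dsb`, `sdsb`,
#'   `cdsb`.
#' @examples
#' set.seed(1)
#' sample_dsb(2.5)
#' @export
sample_dsb <- function(ir_dose) {
  if (ir_dose < 0) stop("ir_dose must be non-negative", call. = FALSE)
  total <- stats::rpois(1L, 35 * ir_dose)
  sdsb <- round(0.7 * total)
  structure(list(ir_dose = ir_dose, total_dsb = total, sdsb = sdsb,
                 cdsb = total - sdsb),
            class = "dsb_input")
}

#' Molecule-count to concentration conversion constants
#'
#' `C = N / (N_A * V_c)` converts `N` molecules in the cytoplasmic volume
#' `V_c` to a molar concentration; `concentration_from_count()` reports it in
#' nM.  The `trans_ratio` actually used on transport arcs is a configurable
#' constant defaulting to 0.00847 nM per molecule; the formula's output
#' (about 8.47e-4 nM for `V_c` = 1.96 pL) is documented alongside but does
#' not override it.
#'
#' @param N_A Avogadro constant (1/mol).
#' @param V_c Cytoplasmic volume (litres; default 1.96 pL).
#' @param trans_ratio nM added to a cytoplasmic mRNA place per transported
#'   molecule.
#' @return A `conversion_constants` record.
#' @export
conversion_constants <- function(N_A = 6.02214076e23, V_c = 1.96e-12,
                                 trans_ratio = 0.00847) {
  stopifnot(N_A > 0, V_c > 0, trans_ratio > 0)
  structure(list(N_A = N_A, V_c = V_c, trans_ratio = trans_ratio),
            class = "conversion_constants")
}

#' @rdname conversion_constants
#' @param n Number of molecules (>= 0).
#' @param constants A `conversion_constants` record.
#' @return For `concentration_from_count`: the concentration in nM.
#' @export
concentration_from_count <- function(n, constants = conversion_constants()) {
  stopifnot(n >= 0)
  if (constants$V_c <= 0) stop("non-positive volume", call. = FALSE)
  n / (constants$N_A * constants$V_c) * 1e9
}

#' Kinetic parameter set for the cell-fate model
#'
#' @param constants Named list of non-negative kinetic constants.
#' @param initial Named numeric vector of initial markings (by place id);
#'   places not named default to 0.
#' @param provenance `"surrogate"` (the shipped oscillatory calibration),
#'   `"iwamoto"` (an externally transcribed literature parameterization) or
#'   `"user"`.
#' @return A `parameter_set` record.
#' @export
parameter_set <- function(constants, initial = numeric(),
                          provenance = c("surrogate", "iwamoto", "user")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(constants), all(vapply(constants, is.numeric, NA)))
  if (any(unlist(constants) < 0))
    stop("kinetic constants must be non-negative", call. = FALSE)
  structure(list(constants = constants, initial = initial,
                 provenance = provenance),
            class = "parameter_set")
}

# ---- model wiring -----------------------------------------------------------
# Reaction shorthand: pre / post are named weight vectors (weights may be
# expression strings), mods is a character vector of modifier places.
.rx <- function(id, rate, pre = NULL, post = NULL, mods = NULL)
  list(id = id, rate = rate, pre = pre, post = post, mods = mods)

.cellfate_nuclear_places <- function() c(
  "IR", "DSB", "SDSB", "CDSB", "MRN", "SDSB_MRN", "CDSB_MRN", "fDSB",
  "ATM", "ATMP", "ATMP_Wip1",
  "p53_mRNA", "p53", "p53_P", "p53_PP",
  "Mdm2_mRNA", "Mdm2", "Mdm2_P",
  "Wip1_mRNA", "Wip1", "DINP1_mRNA", "DINP1",
  "p53_Mdm2", "p53P_Mdm2", "p53PP_Mdm2",
  "p21_mRNA_n", "Bax_mRNA_n", "PIDD_mRNA_n", "Bcl2_mRNA_n")

.cellfate_cyto_places <- function() c(
  "p21_mRNA_c", "Bax_mRNA_c", "PIDD_mRNA_c", "Bcl2_mRNA_c",
  "p21_c", "PIDD_c", "Bax_c", "Bcl2_c",
  "PIDDosome", "Proc2", "Casp2", "Bid", "tBid",
  "Bax_m", "Bcl2_m", "Bax_Bcl2_c", "Bax_Bcl2_m", "Bax2_m", "Bax4_m",
  "Cytc_m", "Cytc_c", "SMAC_m", "SMAC_c", "XIAP", "SMAC_XIAP",
  "Apaf1", "Apaf1_Cytc", "ATP_c", "ADP_c", "Apop",
  "Proc9", "Casp9", "Apop_Proc9",
  "Proc3", "Casp3", "Apop_Proc3",
  "XIAP_Casp3", "XIAP_Proc9", "p21_Proc3",
  "ICAD", "CAD", "CAD_ICAD", "ICAD_frag", "PARP", "cPARP")

.cellfate_nuclear_reactions <- function() list(
  # DSB recognition and repair (MRN recycled on completion)
  .rx("bind_SDSB_MRN", "k_dsb_mrn * SDSB * MRN", pre = c(SDSB = 1, MRN = 1),
      post = c(SDSB_MRN = 1)),
  .rx("bind_CDSB_MRN", "k_dsb_mrn * CDSB * MRN", pre = c(CDSB = 1, MRN = 1),
      post = c(CDSB_MRN = 1)),
  .rx("repair_SDSB", "k_rep_s * SDSB_MRN", pre = c(SDSB_MRN = 1),
      post = c(fDSB = 1, MRN = 1)),
  .rx("repair_CDSB", "k_rep_c * CDSB_MRN", pre = c(CDSB_MRN = 1),
      post = c(fDSB = 1, MRN = 1)),
  # DSB-MRN complexes induce ATM trans-autophosphorylation (autocatalytic in
  # ATMP, so activation is switch-like while damage persists)
  .rx("act_ATM_s", "ATM * SDSB_MRN * (k_atm_act + k_atm_auto * ATMP)",
      pre = c(ATM = 1), post = c(ATMP = 1), mods = c("SDSB_MRN", "ATMP")),
  .rx("act_ATM_c", "ATM * CDSB_MRN * (k_atm_act + k_atm_auto * ATMP)",
      pre = c(ATM = 1), post = c(ATMP = 1), mods = c("CDSB_MRN", "ATMP")),
  # Wip1 deactivates ATMP (negative feedback ATM -> p53 -> Wip1 -> ATM)
  .rx("bind_ATMP_Wip1", "f_aw * ATMP * Wip1 * Wip1",
      pre = c(ATMP = 1, Wip1 = 1), post = c(ATMP_Wip1 = 1)),
  .rx("diss_ATMP_Wip1", "r_aw * ATMP_Wip1", pre = c(ATMP_Wip1 = 1),
      post = c(ATMP = 1, Wip1 = 1)),
  .rx("deph_ATMP", "k_aw_cat * ATMP_Wip1", pre = c(ATMP_Wip1 = 1),
      post = c(ATM = 1, Wip1 = 1)),
  # p53 expression
  .rx("syn_p53_mRNA", "s_p53_mrna", post = c(p53_mRNA = 1)),
  .rx("deg_p53_mRNA", "d_p53_mrna * p53_mRNA", pre = c(p53_mRNA = 1)),
  .rx("syn_p53", "s_p53 * p53_mRNA", post = c(p53 = 1), mods = "p53_mRNA"),
  .rx("deg_p53", "d_p53 * p53", pre = c(p53 = 1)),
  # phosphoform interconversion (ATMP activates Ser15; DINP1 promotes the
  # second site; Wip1 dephosphorylates both)
  .rx("phos_p53", "k_p53_ph * p53 * ATMP", pre = c(p53 = 1),
      post = c(p53_P = 1), mods = "ATMP"),
  .rx("deph_p53P", "k_p53p_deph * p53_P * Wip1", pre = c(p53_P = 1),
      post = c(p53 = 1), mods = "Wip1"),
  .rx("phos_p53P", "k_p53pp_ph * p53_P * DINP1", pre = c(p53_P = 1),
      post = c(p53_PP = 1), mods = "DINP1"),
  .rx("deph_p53PP", "k_p53pp_deph * p53_PP * Wip1", pre = c(p53_PP = 1),
      post = c(p53_P = 1), mods = "Wip1"),
  # Mdm2 expression (p53-P induced) and ATMP-mediated destabilisation
  .rx("syn_Mdm2_mRNA", "s_mdm2_mrna0 + s_mdm2_mrna * p53_P",
      post = c(Mdm2_mRNA = 1), mods = "p53_P"),
  .rx("deg_Mdm2_mRNA", "d_mdm2_mrna * Mdm2_mRNA", pre = c(Mdm2_mRNA = 1)),
  .rx("syn_Mdm2", "s_mdm2 * Mdm2_mRNA", post = c(Mdm2 = 1), mods = "Mdm2_mRNA"),
  .rx("deg_Mdm2", "d_mdm2 * Mdm2", pre = c(Mdm2 = 1)),
  .rx("phos_Mdm2", "k_mdm2_ph * Mdm2 * ATMP", pre = c(Mdm2 = 1),
      post = c(Mdm2_P = 1), mods = "ATMP"),
  .rx("deg_Mdm2P", "d_mdm2p * Mdm2_P", pre = c(Mdm2_P = 1)),
  # Mdm2-mediated degradation of all three p53 forms (complex + turnover,
  # Mdm2 recycled)
  .rx("bind_p53_Mdm2", "f_pm * p53 * Mdm2", pre = c(p53 = 1, Mdm2 = 1),
      post = c(p53_Mdm2 = 1)),
  .rx("diss_p53_Mdm2", "r_pm * p53_Mdm2", pre = c(p53_Mdm2 = 1),
      post = c(p53 = 1, Mdm2 = 1)),
  .rx("deg_p53_Mdm2", "k_pm_deg * p53_Mdm2", pre = c(p53_Mdm2 = 1),
      post = c(Mdm2 = 1)),
  .rx("bind_p53P_Mdm2", "f_pm_p * p53_P * Mdm2", pre = c(p53_P = 1, Mdm2 = 1),
      post = c(p53P_Mdm2 = 1)),
  .rx("diss_p53P_Mdm2", "r_pm * p53P_Mdm2", pre = c(p53P_Mdm2 = 1),
      post = c(p53_P = 1, Mdm2 = 1)),
  .rx("deg_p53P_Mdm2", "k_pm_deg * p53P_Mdm2", pre = c(p53P_Mdm2 = 1),
      post = c(Mdm2 = 1)),
  .rx("bind_p53PP_Mdm2", "f_pm_p * p53_PP * Mdm2", pre = c(p53_PP = 1, Mdm2 = 1),
      post = c(p53PP_Mdm2 = 1)),
  .rx("diss_p53PP_Mdm2", "r_pm * p53PP_Mdm2", pre = c(p53PP_Mdm2 = 1),
      post = c(p53_PP = 1, Mdm2 = 1)),
  .rx("deg_p53PP_Mdm2", "k_pm_deg * p53PP_Mdm2", pre = c(p53PP_Mdm2 = 1),
      post = c(Mdm2 = 1)),
  # Wip1 and p53DINP1 expression (p53-P induced)
  .rx("syn_Wip1_mRNA", "s_wip1_mrna * p53_P", post = c(Wip1_mRNA = 1),
      mods = "p53_P"),
  .rx("deg_Wip1_mRNA", "d_wip1_mrna * Wip1_mRNA", pre = c(Wip1_mRNA = 1)),
  .rx("syn_Wip1", "s_wip1 * Wip1_mRNA", post = c(Wip1 = 1), mods = "Wip1_mRNA"),
  .rx("deg_Wip1", "d_wip1 * Wip1", pre = c(Wip1 = 1)),
  .rx("syn_DINP1_mRNA", "s_dinp1_mrna * p53_P", post = c(DINP1_mRNA = 1),
      mods = "p53_P"),
  .rx("deg_DINP1_mRNA", "d_dinp1_mrna * DINP1_mRNA", pre = c(DINP1_mRNA = 1)),
  .rx("syn_DINP1", "s_dinp1 * DINP1_mRNA", post = c(DINP1 = 1),
      mods = "DINP1_mRNA"),
  .rx("deg_DINP1", "d_dinp1 * DINP1", pre = c(DINP1 = 1)),
  # p53-P induces p21 mRNA; p53-PP induces Bax and PIDD mRNA and represses
  # Bcl2 mRNA
  .rx("syn_p21_mRNA", "s_p21_mrna * p53_P", post = c(p21_mRNA_n = 1),
      mods = "p53_P"),
  .rx("deg_p21_mRNA_n", "d_p21_mrna_n * p21_mRNA_n", pre = c(p21_mRNA_n = 1)),
  .rx("syn_Bax_mRNA", "s_bax_mrna * p53_PP", post = c(Bax_mRNA_n = 1),
      mods = "p53_PP"),
  .rx("deg_Bax_mRNA_n", "d_bax_mrna_n * Bax_mRNA_n", pre = c(Bax_mRNA_n = 1)),
  .rx("syn_PIDD_mRNA", "s_pidd_mrna * p53_PP", post = c(PIDD_mRNA_n = 1),
      mods = "p53_PP"),
  .rx("deg_PIDD_mRNA_n", "d_pidd_mrna_n * PIDD_mRNA_n", pre = c(PIDD_mRNA_n = 1)),
  .rx("syn_Bcl2_mRNA", "s_bcl2_mrna / (1 + k_bcl2_inh * p53_PP)",
      post = c(Bcl2_mRNA_n = 1), mods = "p53_PP"),
  .rx("deg_Bcl2_mRNA_n", "d_bcl2_mrna_n * Bcl2_mRNA_n", pre = c(Bcl2_mRNA_n = 1)),
  # nucleus -> cytoplasm mRNA transport (hybrid bridge; post-weight is the
  # trans ratio, set on the arc in the builder)
  .rx("transport_p21", "k_tr * p21_mRNA_n", pre = c(p21_mRNA_n = 1),
      post = c(p21_mRNA_c = NA)),
  .rx("transport_Bax", "k_tr * Bax_mRNA_n", pre = c(Bax_mRNA_n = 1),
      post = c(Bax_mRNA_c = NA)),
  .rx("transport_PIDD", "k_tr * PIDD_mRNA_n", pre = c(PIDD_mRNA_n = 1),
      post = c(PIDD_mRNA_c = NA)),
  .rx("transport_Bcl2", "k_tr * Bcl2_mRNA_n", pre = c(Bcl2_mRNA_n = 1),
      post = c(Bcl2_mRNA_c = NA)))

.cellfate_cyto_reactions <- function() list(
  # translation of the transported mRNAs and turnover
  .rx("syn_p21_c", "s_p21_c * p21_mRNA_c", post = c(p21_c = 1),
      mods = "p21_mRNA_c"),
  .rx("syn_PIDD_c", "s_pidd_c * PIDD_mRNA_c", post = c(PIDD_c = 1),
      mods = "PIDD_mRNA_c"),
  .rx("syn_Bax_c", "s_bax_c * Bax_mRNA_c", post = c(Bax_c = 1),
      mods = "Bax_mRNA_c"),
  .rx("syn_Bcl2_c", "s_bcl2_c * Bcl2_mRNA_c", post = c(Bcl2_c = 1),
      mods = "Bcl2_mRNA_c"),
  .rx("deg_p21_mRNA_c", "d_p21_mrna_c * p21_mRNA_c", pre = c(p21_mRNA_c = 1)),
  .rx("deg_PIDD_mRNA_c", "d_pidd_mrna_c * PIDD_mRNA_c", pre = c(PIDD_mRNA_c = 1)),
  .rx("deg_Bax_mRNA_c", "d_bax_mrna_c * Bax_mRNA_c", pre = c(Bax_mRNA_c = 1)),
  .rx("deg_Bcl2_mRNA_c", "d_bcl2_mrna_c * Bcl2_mRNA_c", pre = c(Bcl2_mRNA_c = 1)),
  .rx("deg_p21_c", "d_p21_c * p21_c", pre = c(p21_c = 1)),
  .rx("deg_PIDD_c", "d_pidd_c * PIDD_c", pre = c(PIDD_c = 1)),
  .rx("deg_Bax_c", "d_bax_c * Bax_c", pre = c(Bax_c = 1)),
  .rx("deg_Bcl2_c", "d_bcl2_c * Bcl2_c", pre = c(Bcl2_c = 1)),
  # Casp3 clears p21 (releases the brake on apoptosis)
  .rx("deg_p21_Casp3", "k_p21_casp3 * p21_c * Casp3", pre = c(p21_c = 1),
      mods = "Casp3"),
  # PIDD -> PIDDosome -> Casp2 -> tBid axis
  .rx("form_PIDDosome", "k_pidds * PIDD_c", pre = c(PIDD_c = 1),
      post = c(PIDDosome = 1)),
  .rx("syn_Proc2", "s_proc2", post = c(Proc2 = 1)),
  .rx("deg_Proc2", "d_proc2 * Proc2", pre = c(Proc2 = 1)),
  .rx("act_Casp2", "k_casp2 * Proc2 * PIDDosome", pre = c(Proc2 = 1),
      post = c(Casp2 = 1), mods = "PIDDosome"),
  .rx("deg_Casp2", "d_casp2 * Casp2", pre = c(Casp2 = 1)),
  .rx("syn_Bid", "s_bid", post = c(Bid = 1)),
  .rx("deg_Bid", "d_bid * Bid", pre = c(Bid = 1)),
  .rx("cleave_Bid", "k_bid * Bid * Casp2", pre = c(Bid = 1), post = c(tBid = 1),
      mods = "Casp2"),
  .rx("deg_tBid", "d_tbid * tBid", pre = c(tBid = 1)),
  # Bax translocation, Bcl2 antagonism (both compartments), pore assembly
  .rx("transloc_Bax", "k_baxm * Bax_c * tBid", pre = c(Bax_c = 1),
      post = c(Bax_m = 1), mods = "tBid"),
  .rx("retro_Bax", "k_baxc * Bax_m", pre = c(Bax_m = 1), post = c(Bax_c = 1)),
  .rx("bind_BaxBcl2_c", "f_bb * Bax_c * Bcl2_c", pre = c(Bax_c = 1, Bcl2_c = 1),
      post = c(Bax_Bcl2_c = 1)),
  .rx("diss_BaxBcl2_c", "r_bb * Bax_Bcl2_c", pre = c(Bax_Bcl2_c = 1),
      post = c(Bax_c = 1, Bcl2_c = 1)),
  .rx("transloc_Bcl2", "k_bcl2m * Bcl2_c", pre = c(Bcl2_c = 1),
      post = c(Bcl2_m = 1)),
  .rx("bind_BaxBcl2_m", "f_bb * Bax_m * Bcl2_m", pre = c(Bax_m = 1, Bcl2_m = 1),
      post = c(Bax_Bcl2_m = 1)),
  .rx("diss_BaxBcl2_m", "r_bb * Bax_Bcl2_m", pre = c(Bax_Bcl2_m = 1),
      post = c(Bax_m = 1, Bcl2_m = 1)),
  .rx("dimer_Bax", "k_dim * Bax_m * Bax_m", pre = c(Bax_m = 2),
      post = c(Bax2_m = 1)),
  .rx("undim_Bax", "k_undim * Bax2_m", pre = c(Bax2_m = 1), post = c(Bax_m = 2)),
  .rx("tetramer_Bax", "k_tet * Bax2_m * Bax2_m", pre = c(Bax2_m = 2),
      post = c(Bax4_m = 1)),
  .rx("deg_Bax_m", "d_bax_m * Bax_m", pre = c(Bax_m = 1)),
  .rx("deg_Bcl2_m", "d_bcl2_m * Bcl2_m", pre = c(Bcl2_m = 1)),
  # mitochondrial outer-membrane permeabilisation: pore-dependent release
  .rx("rel_Cytc", "k_cytc * Cytc_m * Bax4_m", pre = c(Cytc_m = 1),
      post = c(Cytc_c = 1), mods = "Bax4_m"),
  .rx("rel_SMAC", "k_smac * SMAC_m * Bax4_m", pre = c(SMAC_m = 1),
      post = c(SMAC_c = 1), mods = "Bax4_m"),
  .rx("deg_Cytc_c", "d_cytc_c * Cytc_c", pre = c(Cytc_c = 1)),
  .rx("deg_SMAC_c", "d_smac_c * SMAC_c", pre = c(SMAC_c = 1)),
  # ATP-dependent apoptosome assembly
  .rx("bind_Apaf_Cytc", "f_ac * Apaf1 * Cytc_c", pre = c(Apaf1 = 1, Cytc_c = 1),
      post = c(Apaf1_Cytc = 1)),
  .rx("diss_Apaf_Cytc", "r_ac * Apaf1_Cytc", pre = c(Apaf1_Cytc = 1),
      post = c(Apaf1 = 1, Cytc_c = 1)),
  .rx("form_Apop", "k_apop * Apaf1_Cytc * ATP_c",
      pre = c(Apaf1_Cytc = 1, ATP_c = 1), post = c(Apop = 1, ADP_c = 1)),
  .rx("regen_ATP", "k_atp * ADP_c", pre = c(ADP_c = 1), post = c(ATP_c = 1)),
  .rx("deg_Apop", "d_apop * Apop", pre = c(Apop = 1)),
  # caspase-9 activation by the apoptosome
  .rx("syn_Proc9", "s_proc9", post = c(Proc9 = 1)),
  .rx("deg_Proc9", "d_proc9 * Proc9", pre = c(Proc9 = 1)),
  .rx("bind_Apop_Proc9", "f_ap9 * Apop * Proc9", pre = c(Apop = 1, Proc9 = 1),
      post = c(Apop_Proc9 = 1)),
  .rx("diss_Apop_Proc9", "r_ap9 * Apop_Proc9", pre = c(Apop_Proc9 = 1),
      post = c(Apop = 1, Proc9 = 1)),
  .rx("act_Casp9", "k_c9 * Apop_Proc9", pre = c(Apop_Proc9 = 1),
      post = c(Apop = 1, Casp9 = 1)),
  .rx("deg_Casp9", "d_casp9 * Casp9", pre = c(Casp9 = 1)),
  # caspase-3 activation by the apoptosome and by caspase-9
  .rx("syn_Proc3", "s_proc3", post = c(Proc3 = 1)),
  .rx("deg_Proc3", "d_proc3 * Proc3", pre = c(Proc3 = 1)),
  .rx("bind_Apop_Proc3", "f_ap3 * Apop * Proc3", pre = c(Apop = 1, Proc3 = 1),
      post = c(Apop_Proc3 = 1)),
  .rx("diss_Apop_Proc3", "r_ap3 * Apop_Proc3", pre = c(Apop_Proc3 = 1),
      post = c(Apop = 1, Proc3 = 1)),
  .rx("act_Casp3_apop", "k_c3 * Apop_Proc3", pre = c(Apop_Proc3 = 1),
      post = c(Apop = 1, Casp3 = 1)),
  .rx("act_Casp3_c9", "k_c3c9 * Proc3 * Casp9", pre = c(Proc3 = 1),
      post = c(Casp3 = 1), mods = "Casp9"),
  .rx("deg_Casp3", "d_casp3 * Casp3", pre = c(Casp3 = 1)),
  # XIAP inhibits Casp3 and Proc9; SMAC sequesters XIAP
  .rx("syn_XIAP", "s_xiap", post = c(XIAP = 1)),
  .rx("deg_XIAP", "d_xiap * XIAP", pre = c(XIAP = 1)),
  .rx("bind_XIAP_Casp3", "f_xc3 * XIAP * Casp3", pre = c(XIAP = 1, Casp3 = 1),
      post = c(XIAP_Casp3 = 1)),
  .rx("diss_XIAP_Casp3", "r_xc3 * XIAP_Casp3", pre = c(XIAP_Casp3 = 1),
      post = c(XIAP = 1, Casp3 = 1)),
  .rx("bind_XIAP_Proc9", "f_xp9 * XIAP * Proc9", pre = c(XIAP = 1, Proc9 = 1),
      post = c(XIAP_Proc9 = 1)),
  .rx("diss_XIAP_Proc9", "r_xp9 * XIAP_Proc9", pre = c(XIAP_Proc9 = 1),
      post = c(XIAP = 1, Proc9 = 1)),
  .rx("bind_SMAC_XIAP", "f_sx * SMAC_c * XIAP", pre = c(SMAC_c = 1, XIAP = 1),
      post = c(SMAC_XIAP = 1)),
  .rx("diss_SMAC_XIAP", "r_sx * SMAC_XIAP", pre = c(SMAC_XIAP = 1),
      post = c(SMAC_c = 1, XIAP = 1)),
  # p21 holds procaspase-3 (survival brake)
  .rx("bind_p21_Proc3", "f_p21p3 * p21_c * Proc3", pre = c(p21_c = 1, Proc3 = 1),
      post = c(p21_Proc3 = 1)),
  .rx("diss_p21_Proc3", "r_p21p3 * p21_Proc3", pre = c(p21_Proc3 = 1),
      post = c(p21_c = 1, Proc3 = 1)),
  # execution substrates: CAD release and PARP cleavage (Casp3 readouts)
  .rx("bind_CAD_ICAD", "f_cad * CAD * ICAD", pre = c(CAD = 1, ICAD = 1),
      post = c(CAD_ICAD = 1)),
  .rx("cleave_ICAD", "k_icad * CAD_ICAD * Casp3", pre = c(CAD_ICAD = 1),
      post = c(CAD = 1, ICAD_frag = 1), mods = "Casp3"),
  .rx("cleave_PARP", "k_parp * PARP * Casp3", pre = c(PARP = 1),
      post = c(cPARP = 1), mods = "Casp3"))

#' Build the cell-fate decision hybrid Petri net
#'
#' Assembles the full model: the discrete-stochastic nucleus (DSB
#' generation/repair, ATM activation, the p53 pulse generator with its
#' Mdm2 and Wip1 negative feedback loops, p53-target transcription), the
#' immediate transition `Div_IR` that splits the radiation-induced DSB pool
#' 70/30 into simple/complex breaks through marking-dependent arc weights,
#' four stochastic mRNA transport transitions whose continuous post-arcs
#' carry the trans-ratio weight, and the continuous cytoplasmic apoptosis
#' pathway.  The node census is fixed: 29 discrete places, 52 stochastic
#' transitions, 45 continuous places and 69 continuous transitions (plus the
#' one immediate transition).
#'
#' @param params A [parameter_set()]; every rate constant referenced by the
#'   wiring must be present.
#' @param constants A [conversion_constants()]; `constants$trans_ratio`
#'   becomes the post-arc weight of the transport transitions.
#' @return A validated `hpn` model with observables including `p53` (the
#'   scaled total over all p53-containing places) and `Casp3`.
#' @export
build_cellfate_model <- function(params = surrogate_params(),
                                 constants = conversion_constants()) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(constants, "conversion_constants"))
  nuc <- .cellfate_nuclear_places()
  cyt <- .cellfate_cyto_places()
  rx_n <- .cellfate_nuclear_reactions()
  rx_c <- .cellfate_cyto_reactions()

  needed <- unique(unlist(lapply(c(rx_n, rx_c), function(r)
    setdiff(expr_vars(parse_expr(r$rate)), c(nuc, cyt)))))
  needed <- c(needed, "p53_scale")
  missing_par <- setdiff(needed, names(params$constants))
  if (length(missing_par))
    stop("missing parameter(s): ", paste(sort(missing_par), collapse = ", "),
         call. = FALSE)

  init <- stats::setNames(rep(0, length(nuc) + length(cyt)), c(nuc, cyt))
  if (length(params$initial)) {
    bad <- setdiff(names(params$initial), names(init))
    if (length(bad))
      stop("unknown place(s) in initial markings: ", paste(bad, collapse = ", "),
           call. = FALSE)
    init[names(params$initial)] <- params$initial
  }

  places <- c(
    lapply(nuc, function(p) hpn_place(p, "discrete", init[[p]])),
    lapply(cyt, function(p) hpn_place(p, "continuous", init[[p]])))

  transitions <- list()
  arcs <- list()
  add_rx <- function(r, kind) {
    transitions[[length(transitions) + 1L]] <<-
      hpn_transition(r$id, kind, rate = r$rate)
    for (p in names(r$pre))
      arcs[[length(arcs) + 1L]] <<- hpn_arc(p, r$id, weight = r$pre[[p]])
    for (p in names(r$post)) {
      w <- r$post[[p]]
      if (is.na(w)) w <- "trans_ratio"      # transport bridge arcs
      arcs[[length(arcs) + 1L]] <<- hpn_arc(r$id, p, weight = w)
    }
    for (p in r$mods)
      arcs[[length(arcs) + 1L]] <<- hpn_arc(p, r$id, kind = "modifier")
  }
  for (r in rx_n) add_rx(r, "stochastic")
  for (r in rx_c) add_rx(r, "continuous")

  # immediate DSB divider: consumes the IR token and the sampled DSB pool,
  # splits it 70/30 through marking-dependent weights
  transitions[[length(transitions) + 1L]] <-
    hpn_transition("Div_IR", "immediate", priority = 1L)
  arcs <- c(arcs, list(
    hpn_arc("IR", "Div_IR", weight = "max(IR, 1)"),
    hpn_arc("DSB", "Div_IR", weight = "DSB"),
    hpn_arc("Div_IR", "SDSB", weight = "round(0.7 * DSB)"),
    hpn_arc("Div_IR", "CDSB", weight = "DSB - round(0.7 * DSB)")))

  consts <- params$constants
  consts$trans_ratio <- constants$trans_ratio

  observables <- list(
    p53 = "p53_scale * (p53 + p53_P + p53_PP + p53_Mdm2 + p53P_Mdm2 + p53PP_Mdm2)",
    Mdm2 = "Mdm2 + Mdm2_P + p53_Mdm2 + p53P_Mdm2 + p53PP_Mdm2",
    ATMP = "ATMP",
    Wip1 = "Wip1",
    DSB_open = "SDSB + CDSB + SDSB_MRN + CDSB_MRN",
    Bax_c = "Bax_c",
    Bcl2_c = "Bcl2_c",
    Casp3 = "Casp3")

  model <- hpn_model(places, transitions, arcs, constants = consts,
                     observables = observables, name = "cellfate")
  attr(model, "provenance") <- params$provenance
  model
}

#' Census of a model's nodes by kind
#'
#' @param model An `hpn` model.
#' @return Named integer vector: counts of discrete/continuous places and
#'   stochastic/continuous/immediate transitions.
#' @export
hpn_census <- function(model) {
  kp <- vapply(model$places, `[[`, "", "kind")
  kt <- vapply(model$transitions, `[[`, "", "kind")
  c(discrete_places = sum(kp == "discrete"),
    continuous_places = sum(kp == "continuous"),
    stochastic_transitions = sum(kt == "stochastic"),
    continuous_transitions = sum(kt == "continuous"),
    immediate_transitions = sum(kt == "immediate"))
}

#' The shipped surrogate parameterization
#'
#' Loads the frozen surrogate kinetic constants and initial markings from the
#' package's `extdata`.  The surrogate is calibrated only to the qualitative
#' regime: dose-dependent numbers of total-p53 pulses at the single-cell
#' level and damped population-mean oscillation; it does not reproduce any
#' published literature parameterization (load one with
#' [read_parameter_set()] to switch regimes).
#'
#' @return A `parameter_set` with provenance `"surrogate"`.
#' @export
surrogate_params <- function() {
  path <- system.file("extdata", "params_surrogate.txt", package = "hpnfate",
                      mustWork = TRUE)
  read_parameter_set(path)
}
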