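# Surrogate kinetic parameterization of the cell-fate HPN.
# Units: time in hours, discrete markings in molecules, continuous markings
# in nM; the total-p53 observable is scaled by p53_scale into trace units.
# Calibrated only to the qualitative regime: a quiescent no-stress baseline,
# dose-dependent numbers of total-p53 pulses at the single-cell level, and
# damped population-mean oscillation.  Not a transcription of any published
# constant table.
provenance = surrogate

[constants]
# DSB recognition / repair (MRN recycled on completion)
k_dsb_mrn = 1.0
k_rep_s = 0.4
k_rep_c = 0.2
# ATM trans-autophosphorylation (damage-gated, autocatalytic) and
# cooperative Wip1-mediated deactivation
k_atm_act = 0.015
k_atm_auto = 0.04
f_aw = 0.012
r_aw = 0.1
k_aw_cat = 5
# p53 expression; basal turnover acts on the unphosphorylated form only
s_p53_mrna = 15
d_p53_mrna = 0.5
s_p53 = 1.9
d_p53 = 3.5
# p53 phosphoforms (Ser15 phosphorylation escapes basal turnover and has
# reduced Mdm2 affinity)
k_p53_ph = 0.5
k_p53p_deph = 0.05
k_p53pp_ph = 0.05
k_p53pp_deph = 0.12
# Mdm2 expression and ATMP-mediated destabilisation
s_mdm2_mrna0 = 20
s_mdm2_mrna = 2
d_mdm2_mrna = 1
s_mdm2 = 2
d_mdm2 = 0.2
k_mdm2_ph = 0.2
d_mdm2p = 5
# Mdm2-mediated p53 degradation (complex-mediated, Mdm2 recycled)
f_pm = 0.07
f_pm_p = 0.01
r_pm = 1
k_pm_deg = 20
# Wip1
s_wip1_mrna = 0.5
d_wip1_mrna = 0.4
s_wip1 = 3
d_wip1 = 1.2
# p53DINP1
s_dinp1_mrna = 0.2
d_dinp1_mrna = 0.5
s_dinp1 = 2
d_dinp1 = 0.8
# p53 target mRNAs (nucleus) and transport
s_p21_mrna = 0.05
d_p21_mrna_n = 0.3
s_bax_mrna = 0.2
d_bax_mrna_n = 0.3
s_pidd_mrna = 0.15
d_pidd_mrna_n = 0.3
s_bcl2_mrna = 2
k_bcl2_inh = 2
d_bcl2_mrna_n = 0.3
k_tr = 1
# trace-unit scale of the total-p53 observable
p53_scale = 40
# cytoplasm: translation and turnover
s_p21_c = 30
s_pidd_c = 30
s_bax_c = 30
s_bcl2_c = 30
d_p21_mrna_c = 0.5
d_pidd_mrna_c = 0.5
d_bax_mrna_c = 0.5
d_bcl2_mrna_c = 0.5
d_p21_c = 0.3
d_pidd_c = 0.3
d_bax_c = 0.2
d_bcl2_c = 0.2
k_p21_casp3 = 1
# PIDD -> Casp2 -> tBid
k_pidds = 0.1
s_proc2 = 0.6
d_proc2 = 0.2
k_casp2 = 0.5
d_casp2 = 0.3
s_bid = 0.6
d_bid = 0.2
k_bid = 0.5
d_tbid = 0.3
# Bax / Bcl2 and pore assembly
k_baxm = 0.5
k_baxc = 0.2
f_bb = 0.5
r_bb = 0.1
k_bcl2m = 0.1
k_dim = 0.2
k_undim = 0.1
k_tet = 0.2
d_bax_m = 0.1
d_bcl2_m = 0.1
# MOMP release
k_cytc = 0.3
k_smac = 0.3
d_cytc_c = 0.1
d_smac_c = 0.1
# apoptosome
f_ac = 0.2
r_ac = 0.1
k_apop = 0.1
k_atp = 1
d_apop = 0.1
# caspase-9
s_proc9 = 0.4
d_proc9 = 0.2
f_ap9 = 0.3
r_ap9 = 0.1
k_c9 = 1
d_casp9 = 0.3
# caspase-3
s_proc3 = 0.4
d_proc3 = 0.2
f_ap3 = 0.3
r_ap3 = 0.1
k_c3 = 1
k_c3c9 = 0.5
d_casp3 = 0.3
# XIAP / SMAC
s_xiap = 0.4
d_xiap = 0.2
f_xc3 = 0.5
r_xc3 = 0.05
f_xp9 = 0.3
r_xp9 = 0.05
f_sx = 0.5
r_sx = 0.05
# p21 brake
f_p21p3 = 0.3
r_p21p3 = 0.1
# execution substrates
f_cad = 0.5
k_icad = 0.5
k_parp = 0.3

[initial]
MRN = 12
ATM = 20
p53_mRNA = 30
p53 = 5
Mdm2_mRNA = 20
Mdm2 = 115
Cytc_m = 50
SMAC_m = 40
Apaf1 = 20
ATP_c = 100
Proc9 = 2
Proc3 = 2
XIAP = 2
Proc2 = 3
Bid = 3
ICAD = 5
CAD_ICAD = 10
PARP = 50
Bcl2_c = 4
Bax_c = 1
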