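# Targeted NAD metabolomics inclusion list: protonated-ion formulas, per-row
# electron convention, printed accurate mass (Da), t-SIM inclusion window (m/z)
# and retention time (min). The NADPH printed mass matches no single-electron
# convention and is stored verbatim (convention "as-printed").
name,ion_formula,convention,printed_mass_da,inclusion_center_mz,inclusion_halfwidth_mz,rt_min
NAD+,C21H28N7O14P2,none,664.11695,665.0,8,11.02
NADH,C21H30N7O14P2,minus-1e,666.13205,665.0,8,5.57
NADP+,C21H29N7O17P3,minus-1e,744.08273,745.0,8,10.54
NADPH,C21H31N7O17P3,as-printed,746.09783,745.0,8,10.57
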