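surface,functional,dE_kJmol,dE_disp_kJmol,dE_disp_post_md_kJmol
4.5 OH/nm2,PBE,-30.8,,
4.5 OH/nm2,PBE-D2,-10.1,-104.9,-128.0
1.5 OH/nm2,PBE,-38.7,,
1.5 OH/nm2,PBE-D2,-28.2,-131.9,-100.2
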