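name,D0_cm2_per_s,radius_nm,generation_mmol_per_h,physiological_mM,target_L_per_h,source_note
urea,1.38e-5,0.26,,4.6,2.3,"D0 and radius from diffusion literature (37 C); generation rate unavailable, only the target-clearance ratio is bundled"
creatinine,1.0e-5,0.33,0.58,0.11,,"D0 and radius literature values (37 C)"
beta2-microglobulin,1.3e-6,1.6,7.7e-4,1.5e-4,,"D0 and radius literature values for an ~12 kDa globular protein"
albumin,6.1e-7,3.55,1.0e-2,0.65,,"classical literature D0 and Stokes radius for serum albumin"
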