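region,lobe,base_volume_ml,residual_sd_ml
orbitofrontal_cortex,cortical,22.0,1.32
dorsolateral_prefrontal_cortex,cortical,45.0,2.70
ventromedial_prefrontal_cortex,cortical,12.0,0.72
motor_cortex,cortical,30.0,1.80
opercular_cortex,cortical,18.0,1.08
frontal_pole,cortical,12.0,0.72
medial_temporal_cortex,cortical,14.0,0.84
lateral_temporal_cortex,cortical,40.0,2.40
temporal_pole,cortical,15.0,0.90
supratemporal_cortex,cortical,22.0,1.32
medial_parietal_cortex,cortical,18.0,1.08
lateral_parietal_cortex,cortical,40.0,2.40
sensory_cortex,cortical,25.0,1.50
occipital_cortex,cortical,45.0,2.70
anterior_cingulate_cortex,cortical,12.0,0.72
middle_cingulate_cortex,cortical,10.0,0.60
posterior_cingulate_cortex,cortical,10.0,0.60
anterior_insula_cortex,cortical,8.0,0.48
posterior_insula_cortex,cortical,6.0,0.36
amygdala,subcortical,3.2,0.19
hippocampus,subcortical,7.5,0.45
caudate,subcortical,7.8,0.47
putamen,subcortical,9.8,0.59
nucleus_accumbens,subcortical,1.2,0.07
globus_pallidus,subcortical,3.4,0.20
thalamus,subcortical,15.6,0.94
cerebellum,cerebellum,140.0,8.40
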