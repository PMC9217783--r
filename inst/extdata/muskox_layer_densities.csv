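subject_id,region,partition_label,structure,density,unit_scale
old_male,prefrontal,I,neuropil_thread,26.38,per_cm3
old_male,prefrontal,I,neuritic_thread_cluster,5.05,per_cm3
old_male,prefrontal,I,neuron,0.04,per_cm3
old_male,prefrontal,II,neuropil_thread,24.15,per_cm3
old_male,prefrontal,II,neuritic_thread_cluster,4.66,per_cm3
old_male,prefrontal,II,neuron,0.35,per_cm3
old_male,prefrontal,III,neuropil_thread,12.81,per_cm3
old_male,prefrontal,III,neuritic_thread_cluster,2.01,per_cm3
old_male,prefrontal,III,neuron,0.09,per_cm3
old_male,prefrontal,IV-VI,neuropil_thread,15.26,per_cm3
old_male,prefrontal,IV-VI,neuritic_thread_cluster,0.83,per_cm3
old_male,prefrontal,IV-VI,neuron,0.19,per_cm3
old_male,prefrontal,WM,neuropil_thread,2.58,per_cm3
old_male,prefrontal,WM,neuritic_thread_cluster,0.14,per_cm3
old_male,prefrontal,WM,neuron,0.02,per_cm3
old_male,parietal,I,neuropil_thread,46.56,per_cm3
old_male,parietal,I,neuritic_thread_cluster,0.16,per_cm3
old_male,parietal,I,neuron,0,per_cm3
old_male,parietal,II,neuropil_thread,31.58,per_cm3
old_male,parietal,II,neuritic_thread_cluster,0.95,per_cm3
old_male,parietal,II,neuron,0,per_cm3
old_male,parietal,III,neuropil_thread,15.74,per_cm3
old_male,parietal,III,neuritic_thread_cluster,0.81,per_cm3
old_male,parietal,III,neuron,0,per_cm3
old_male,parietal,IV-VI,neuropil_thread,13.72,per_cm3
old_male,parietal,IV-VI,neuritic_thread_cluster,0.48,per_cm3
old_male,parietal,IV-VI,neuron,0.1,per_cm3
old_male,parietal,WM,neuropil_thread,2.67,per_cm3
old_male,parietal,WM,neuritic_thread_cluster,0,per_cm3
old_male,parietal,WM,neuron,0,per_cm3
middle_aged_female,prefrontal,I,neuropil_thread,838.06,per_cm3
middle_aged_female,prefrontal,I,neuritic_thread_cluster,102.55,per_cm3
middle_aged_female,prefrontal,I,neuron,0.3,per_cm3
middle_aged_female,prefrontal,II,neuropil_thread,606.09,per_cm3
middle_aged_female,prefrontal,II,neuritic_thread_cluster,76.88,per_cm3
middle_aged_female,prefrontal,II,neuron,5.06,per_cm3
middle_aged_female,prefrontal,III,neuropil_thread,386.74,per_cm3
middle_aged_female,prefrontal,III,neuritic_thread_cluster,46.31,per_cm3
middle_aged_female,prefrontal,III,neuron,1.56,per_cm3
middle_aged_female,prefrontal,IV-VI,neuropil_thread,310.93,per_cm3
middle_aged_female,prefrontal,IV-VI,neuritic_thread_cluster,36.71,per_cm3
middle_aged_female,prefrontal,IV-VI,neuron,1.66,per_cm3
middle_aged_female,prefrontal,WM,neuropil_thread,84.21,per_cm3
middle_aged_female,prefrontal,WM,neuritic_thread_cluster,7.8,per_cm3
middle_aged_female,prefrontal,WM,neuron,0,per_cm3
middle_aged_female,parietal,I,neuropil_thread,68.31,per_cm3
middle_aged_female,parietal,I,neuritic_thread_cluster,0.82,per_cm3
middle_aged_female,parietal,I,neuron,0,per_cm3
middle_aged_female,parietal,II,neuropil_thread,31.34,per_cm3
middle_aged_female,parietal,II,neuritic_thread_cluster,0.72,per_cm3
middle_aged_female,parietal,II,neuron,0.18,per_cm3
middle_aged_female,parietal,III,neuropil_thread,19.11,per_cm3
middle_aged_female,parietal,III,neuritic_thread_cluster,0.54,per_cm3
middle_aged_female,parietal,III,neuron,0,per_cm3
middle_aged_female,parietal,IV-VI,neuropil_thread,24.9,per_cm3
middle_aged_female,parietal,IV-VI,neuritic_thread_cluster,0.39,per_cm3
middle_aged_female,parietal,IV-VI,neuron,0,per_cm3
middle_aged_female,parietal,WM,neuropil_thread,3.81,per_cm3
middle_aged_female,parietal,WM,neuritic_thread_cluster,0.04,per_cm3
middle_aged_female,parietal,WM,neuron,0,per_cm3
old_female,prefrontal,I,neuropil_thread,14345.69,per_cm3
old_female,prefrontal,I,neuritic_thread_cluster,380.7,per_cm3
old_female,prefrontal,I,neuron,0,per_cm3
old_female,prefrontal,II,neuropil_thread,9049.63,per_cm3
old_female,prefrontal,II,neuritic_thread_cluster,856.97,per_cm3
old_female,prefrontal,II,neuron,0,per_cm3
old_female,prefrontal,III,neuropil_thread,6385.27,per_cm3
old_female,prefrontal,III,neuritic_thread_cluster,349.36,per_cm3
old_female,prefrontal,III,neuron,6.24,per_cm3
old_female,prefrontal,IV-VI,neuropil_thread,6306.02,per_cm3
old_female,prefrontal,IV-VI,neuritic_thread_cluster,292.55,per_cm3
old_female,prefrontal,IV-VI,neuron,24.38,per_cm3
old_female,prefrontal,WM,neuropil_thread,1428.71,per_cm3
old_female,prefrontal,WM,neuritic_thread_cluster,91,per_cm3
old_female,prefrontal,WM,neuron,0,per_cm3
old_female,parietal,I,neuropil_thread,164.73,per_cm3
old_female,parietal,I,neuritic_thread_cluster,6.13,per_cm3
old_female,parietal,I,neuron,0,per_cm3
old_female,parietal,II,neuropil_thread,239.71,per_cm3
old_female,parietal,II,neuritic_thread_cluster,12.51,per_cm3
old_female,parietal,II,neuron,0.48,per_cm3
old_female,parietal,III,neuropil_thread,74.79,per_cm3
old_female,parietal,III,neuritic_thread_cluster,3.58,per_cm3
old_female,parietal,III,neuron,0.05,per_cm3
old_female,parietal,IV-VI,neuropil_thread,27.55,per_cm3
old_female,parietal,IV-VI,neuritic_thread_cluster,2.02,per_cm3
old_female,parietal,IV-VI,neuron,0,per_cm3
old_female,parietal,WM,neuropil_thread,7.81,per_cm3
old_female,parietal,WM,neuritic_thread_cluster,0.14,per_cm3
old_female,parietal,WM,neuron,0.07,per_cm3
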