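measure,timepoint,units,control_mean,control_sem,control_n,smndelta7_mean,smndelta7_sem,smndelta7_n
mepp_amplitude,P12-14,mV,0.61,0.03,NA,0.82,0.03,NA
mepp_frequency,P12-14,per_min,8.97,0.99,NA,3.16,0.26,NA
epp_amplitude,P12-14,mV,7.27,0.34,NA,7.53,0.31,NA
quantal_content,P12-14,dimensionless,13.20,0.77,NA,9.97,0.45,NA
paired_pulse_ratio,P12-14,percent,119.4,3.54,14,145.9,12.5,9
rrp_size,P12-14,quanta,640.2,77.1,15,625.4,54.8,14
release_probability,P12-14,dimensionless,0.027,0.003,15,0.020,0.001,14
stim_ratio_1hz,P12-14,dimensionless,0.97,0.03,9,1.07,0.07,9
stim_ratio_10hz,P12-14,dimensionless,0.98,0.02,9,1.09,0.08,9
stim_ratio_40hz,P12-14,dimensionless,0.99,0.04,9,1.03,0.05,9
stim_ratio_100hz,P12-14,dimensionless,1.02,0.03,9,1.00,0.05,9
specific_force,P12-14,g_per_mm2,4.48,0.54,7,4.23,0.99,8
muscle_csa,P12-14,mm2,0.46,0.02,NA,0.23,0.02,NA
synapse_count,P14,per_neuron,64.3,3.6,180,46.1,3.7,163
synapse_density,P4,per_100um,41.4,5.2,64,45.8,7.4,46
synapse_density,P7,per_100um,53.9,4.1,48,53.2,4.6,83
synapse_density,P14,per_100um,56.4,3.2,180,44.4,2.7,163
em_terminal_density,P14,per_100um,55.8,5.8,8,40.8,6.0,11
em_psd_bouton_density,P14,per_100um,30.2,5.7,8,14.7,2.0,11
dorsal_root_axons,P14,count,1707,20,6,1577,27,7
pv_cells,P14,count,1138,27,6,985,29,4
microglia_density,P4,per_section,49.0,2.1,4,65.5,4.5,4
microglia_density,P7,per_section,41.7,6.6,4,58.3,9.0,4
microglia_density,P10,per_section,50.1,3.2,4,82.1,8.7,4
microglia_density,P14,per_section,68.4,6.1,4,112.7,6.2,4
microglia_association,P7,percent,12.4,0.9,4,12.5,1.6,4
microglia_association,P14,percent,11.3,1.4,6,19.6,2.2,6
psd_length_fraction,P14,percent,22.0,2.0,10,14.6,1.9,15
bouton_size,P14,um,1.26,0.05,162,1.31,0.06,160
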