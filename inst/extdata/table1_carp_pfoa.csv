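feature,subindex,direction,units,representative_stat,unexposed,PFOA_200ng_L,PFOA_2mg_L
pedicel_width,nephrotoxic,1,nm,mean,228,228,286
basement_membrane_thickness,nephrotoxic,1,nm,mean,146,146,237
fenestrae_width,nephrotoxic,1,nm,mean,136,136,180
proximal_tubule_vesiculations,nephrotoxic,1,area ratio,ratio,0.0357,0.0557,0.0918
collecting_duct_rodlet_cells,nephrotoxic,1,cells/field,mean,0,0.01,0.35
total_thyroid_follicles,thyrotoxic,1,follicles/section,mean,5.00,42.33,20.29
vesiculated_thyroid_follicles,thyrotoxic,1,follicles/section,mean,1.33,28.50,13.57
follicle_cross_sectional_area,thyrotoxic,-1,um^2,median,829,295,461
follicle_perimeter,thyrotoxic,-1,um,median,113,69,86
hematopoietic_rodlet_cells,immunotoxic,1,cells/field,mean,0.81,4.02,6.47
effete_rodlet_cells,immunotoxic,1,cell ratio,ratio,0.1,0.2,0.35
rodlet_cell_degranulation,immunotoxic,1,factor score,factor_score,-0.98438,0.292708,0.022556
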