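subject,sig_area_mm2,trend_area_mm2,total_area_mm2,depth_slope,sagittal_angle_deg,axial_angle_deg,r2,initial_depth_mm
1,30,62,121,0.59,-22,11,0.43,0.57
2,19,38,138,0.68,7,8,0.62,0.90
3,32,72,182,0.49,-34,21,0.57,0.72
4,19,42,110,0.36,-17,33,0.37,0.71
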