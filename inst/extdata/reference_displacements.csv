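design,quantity,tooth,value
con,md_displacement,1,0.11
con,md_displacement,2,0.35
con,md_displacement,3,0.73
con,md_displacement,4,-1.69
con,md_displacement,5,-1.7
con,md_displacement,6,0.41
con,md_displacement,7,0.41
smhw,md_displacement,1,0.14
smhw,md_displacement,2,0.44
smhw,md_displacement,3,0.92
smhw,md_displacement,4,-1.5
smhw,md_displacement,5,-1.51
smhw,md_displacement,6,0.6
smhw,md_displacement,7,0.11
mhw,md_displacement,1,0.18
mhw,md_displacement,2,0.57
mhw,md_displacement,3,1.19
mhw,md_displacement,4,-1.91
mhw,md_displacement,5,-1.93
mhw,md_displacement,6,0.17
mhw,md_displacement,7,0.02
con,bl_displacement,1,-0.66
con,bl_displacement,2,-0.66
con,bl_displacement,3,-0.35
con,bl_displacement,4,0.16
con,bl_displacement,5,0.16
con,bl_displacement,6,-0.02
con,bl_displacement,7,-0.01
smhw,bl_displacement,1,-0.83
smhw,bl_displacement,2,-0.83
smhw,bl_displacement,3,-0.43
smhw,bl_displacement,4,0.15
smhw,bl_displacement,5,0.14
smhw,bl_displacement,6,-0.11
smhw,bl_displacement,7,-0.04
mhw,bl_displacement,1,-1.08
mhw,bl_displacement,2,-1.06
mhw,bl_displacement,3,-0.51
mhw,bl_displacement,4,0.13
mhw,bl_displacement,5,0.14
mhw,bl_displacement,6,-0.02
mhw,bl_displacement,7,-0.01
con,axial_displacement,1,0.03
con,axial_displacement,2,0.02
con,axial_displacement,3,-0.07
con,axial_displacement,4,0.22
con,axial_displacement,5,0.29
con,axial_displacement,6,0.17
con,axial_displacement,7,0.17
smhw,axial_displacement,1,0.05
smhw,axial_displacement,2,0.02
smhw,axial_displacement,3,-0.07
smhw,axial_displacement,4,0.2
smhw,axial_displacement,5,0.24
smhw,axial_displacement,6,0.21
smhw,axial_displacement,7,0.06
mhw,axial_displacement,1,0.06
mhw,axial_displacement,2,0.02
mhw,axial_displacement,3,-0.08
mhw,axial_displacement,4,0.19
mhw,axial_displacement,5,0.23
mhw,axial_displacement,6,0.13
mhw,axial_displacement,7,0.01
con,bl_torque,1,-1.82
con,bl_torque,2,-1.44
con,bl_torque,3,-1.27
con,bl_torque,4,1.73
con,bl_torque,5,1.71
con,bl_torque,6,0.44
con,bl_torque,7,0.88
smhw,bl_torque,1,-2.38
smhw,bl_torque,2,-1.68
smhw,bl_torque,3,-1.39
smhw,bl_torque,4,1.51
smhw,bl_torque,5,1.22
smhw,bl_torque,6,0.2
smhw,bl_torque,7,0.19
mhw,bl_torque,1,-3.19
mhw,bl_torque,2,-2.81
mhw,bl_torque,3,-1.48
mhw,bl_torque,4,1.4
mhw,bl_torque,5,1.12
mhw,bl_torque,6,0.06
mhw,bl_torque,7,0.02
con,md_tipping,1,-0.18
con,md_tipping,2,-0.38
con,md_tipping,3,-2.15
con,md_tipping,4,4.1
con,md_tipping,5,4.55
con,md_tipping,6,-1.78
con,md_tipping,7,-1.93
smhw,md_tipping,1,-0.19
smhw,md_tipping,2,-0.59
smhw,md_tipping,3,-2.31
smhw,md_tipping,4,3.65
smhw,md_tipping,5,4.18
smhw,md_tipping,6,-2.02
smhw,md_tipping,7,-0.8
mhw,md_tipping,1,-0.22
mhw,md_tipping,2,-0.73
mhw,md_tipping,3,-2.62
mhw,md_tipping,4,5.49
mhw,md_tipping,5,5.08
mhw,md_tipping,6,-1.52
mhw,md_tipping,7,-0.2
con,axial_rotation,1,0.53
con,axial_rotation,2,0.59
con,axial_rotation,3,0.63
con,axial_rotation,4,1.23
con,axial_rotation,5,2.13
con,axial_rotation,6,0.16
con,axial_rotation,7,0.2
smhw,axial_rotation,1,0.42
smhw,axial_rotation,2,0.37
smhw,axial_rotation,3,0.44
smhw,axial_rotation,4,1.07
smhw,axial_rotation,5,1.95
smhw,axial_rotation,6,0.22
smhw,axial_rotation,7,0.12
mhw,axial_rotation,1,0.53
mhw,axial_rotation,2,0.38
mhw,axial_rotation,3,0.38
mhw,axial_rotation,4,1.11
mhw,axial_rotation,5,1.92
mhw,axial_rotation,6,0.14
mhw,axial_rotation,7,0.04
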