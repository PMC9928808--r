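model,parameter,c0,c11,c12,c21,c22
table1_1dof,tf_lateral_shift,1.57,-0.0488,,1.37E-04,
table1_1dof,tf_anterior_drawer,0.58,0.0390,,4.74E-04,
table1_1dof,tf_joint_distraction,-1.74,0.0161,,-3.47E-04,
table1_1dof,tf_abduction,-4.79,-0.0213,,3.79E-04,
table1_1dof,tf_external_rotation,-0.16,-0.1944,,1.39E-03,
table1_1dof,pf_lateral_shift,4.78,-0.0433,,3.71E-04,
table1_1dof,pf_anterior_translation,49.59,-0.0940,,-6.86E-04,
table1_1dof,pf_superior_translation,13.21,-0.2192,,7.15E-04,
table1_1dof,pf_flexion,0.30,0.6284,,6.49E-04,
table1_1dof,pf_lateral_rotation,-3.87,0.0019,,2.34E-04,
table1_1dof,pf_lateral_tilt,1.08,0.0328,,-2.90E-04,
table1_2dof,tf_lateral_shift,1.54,-0.0585,-0.029,2.00E-04,2.35E-03
table1_2dof,tf_anterior_drawer,0.51,0.0014,-0.155,7.32E-04,4.30E-03
table1_2dof,tf_joint_distraction,-1.76,0.0220,0.053,-3.96E-04,2.61E-03
table1_2dof,tf_abduction,-4.87,-0.0567,-0.136,6.19E-04,5.16E-03
table1_2dof,pf_lateral_shift,4.76,-0.0252,0.121,2.33E-04,3.21E-03
table1_2dof,pf_anterior_translation,49.63,-0.0694,0.108,-8.57E-04,-2.09E-03
table1_2dof,pf_superior_translation,13.26,-0.1907,0.124,5.17E-04,-2.54E-03
table1_2dof,pf_flexion,0.42,0.7115,0.382,6.71E-05,-5.14E-03
table1_2dof,pf_lateral_rotation,-3.83,-0.0558,-0.371,6.71E-04,-8.38E-03
table1_2dof,pf_lateral_tilt,1.15,0.0851,0.244,-6.58E-04,-2.89E-03
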