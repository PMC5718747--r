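tissue,energy_MeV,Zeq
adipose_tissue,0.015,6.39
blood_whole,0.015,7.56
cortical_bone,0.015,12.99
brain,0.015,7.5
breast_tissue,0.015,6.96
eye_lens,0.015,7.25
lung_tissue,0.015,7.52
skeletal_muscle,0.015,7.49
ovary,0.015,7.5
testis,0.015,7.47
soft_tissue,0.015,7.5
soft_tissue_4component,0.015,7.28
adipose_tissue,0.02,6.41
blood_whole,0.02,7.61
cortical_bone,0.02,13.18
brain,0.02,7.54
breast_tissue,0.02,7.0
eye_lens,0.02,7.28
lung_tissue,0.02,7.56
skeletal_muscle,0.02,7.53
ovary,0.02,7.53
testis,0.02,7.51
soft_tissue,0.02,7.54
soft_tissue_4component,0.02,7.31
adipose_tissue,0.03,6.43
blood_whole,0.03,7.66
cortical_bone,0.03,13.4
brain,0.03,7.58
breast_tissue,0.03,7.05
eye_lens,0.03,7.31
lung_tissue,0.03,7.6
skeletal_muscle,0.03,7.57
ovary,0.03,7.57
testis,0.03,7.54
soft_tissue,0.03,7.58
soft_tissue_4component,0.03,7.33
adipose_tissue,0.04,6.44
blood_whole,0.04,7.68
cortical_bone,0.04,13.53
brain,0.04,7.61
breast_tissue,0.04,7.06
eye_lens,0.04,7.32
lung_tissue,0.04,7.62
skeletal_muscle,0.04,7.59
ovary,0.04,7.59
testis,0.04,7.56
soft_tissue,0.04,7.6
soft_tissue_4component,0.04,7.33
adipose_tissue,0.05,6.45
blood_whole,0.05,7.71
cortical_bone,0.05,13.62
brain,0.05,7.62
breast_tissue,0.05,7.08
eye_lens,0.05,7.33
lung_tissue,0.05,7.64
skeletal_muscle,0.05,7.61
ovary,0.05,7.6
testis,0.05,7.57
soft_tissue,0.05,7.61
soft_tissue_4component,0.05,7.34
adipose_tissue,0.06,6.46
blood_whole,0.06,7.72
cortical_bone,0.06,13.69
brain,0.06,7.64
breast_tissue,0.06,7.08
eye_lens,0.06,7.34
lung_tissue,0.06,7.65
skeletal_muscle,0.06,7.62
ovary,0.06,7.61
testis,0.06,7.58
soft_tissue,0.06,7.63
soft_tissue_4component,0.06,7.34
adipose_tissue,0.08,6.47
blood_whole,0.08,7.75
cortical_bone,0.08,13.78
brain,0.08,7.66
breast_tissue,0.08,7.09
eye_lens,0.08,7.34
lung_tissue,0.08,7.66
skeletal_muscle,0.08,7.64
ovary,0.08,7.62
testis,0.08,7.59
soft_tissue,0.08,7.65
soft_tissue_4component,0.08,7.34
adipose_tissue,0.1,6.48
blood_whole,0.1,7.77
cortical_bone,0.1,13.84
brain,0.1,7.67
breast_tissue,0.1,7.1
eye_lens,0.1,7.35
lung_tissue,0.1,7.68
skeletal_muscle,0.1,7.65
ovary,0.1,7.63
testis,0.1,7.6
soft_tissue,0.1,7.66
soft_tissue_4component,0.1,7.35
adipose_tissue,0.15,6.49
blood_whole,0.15,7.8
cortical_bone,0.15,13.94
brain,0.15,7.69
breast_tissue,0.15,7.11
eye_lens,0.15,7.36
lung_tissue,0.15,7.7
skeletal_muscle,0.15,7.67
ovary,0.15,7.65
testis,0.15,7.62
soft_tissue,0.15,7.68
soft_tissue_4component,0.15,7.35
adipose_tissue,0.2,6.49
blood_whole,0.2,7.81
cortical_bone,0.2,14.0
brain,0.2,7.71
breast_tissue,0.2,7.12
eye_lens,0.2,7.37
lung_tissue,0.2,7.71
skeletal_muscle,0.2,7.69
ovary,0.2,7.66
testis,0.2,7.63
soft_tissue,0.2,7.69
soft_tissue_4component,0.2,7.35
adipose_tissue,0.3,6.5
blood_whole,0.3,7.83
cortical_bone,0.3,14.06
brain,0.3,7.72
breast_tissue,0.3,7.12
eye_lens,0.3,7.37
lung_tissue,0.3,7.72
skeletal_muscle,0.3,7.7
ovary,0.3,7.67
testis,0.3,7.64
soft_tissue,0.3,7.71
soft_tissue_4component,0.3,7.36
adipose_tissue,0.4,6.5
blood_whole,0.4,7.84
cortical_bone,0.4,14.09
brain,0.4,7.73
breast_tissue,0.4,7.13
eye_lens,0.4,7.38
lung_tissue,0.4,7.73
skeletal_muscle,0.4,7.71
ovary,0.4,7.68
testis,0.4,7.64
soft_tissue,0.4,7.71
soft_tissue_4component,0.4,7.36
adipose_tissue,0.5,6.5
blood_whole,0.5,7.85
cortical_bone,0.5,14.1
brain,0.5,7.73
breast_tissue,0.5,7.13
eye_lens,0.5,7.38
lung_tissue,0.5,7.73
skeletal_muscle,0.5,7.71
ovary,0.5,7.68
testis,0.5,7.65
soft_tissue,0.5,7.72
soft_tissue_4component,0.5,7.36
adipose_tissue,0.6,6.51
blood_whole,0.6,7.86
cortical_bone,0.6,14.11
brain,0.6,7.74
breast_tissue,0.6,7.13
eye_lens,0.6,7.38
lung_tissue,0.6,7.73
skeletal_muscle,0.6,7.71
ovary,0.6,7.68
testis,0.6,7.65
soft_tissue,0.6,7.72
soft_tissue_4component,0.6,7.36
adipose_tissue,0.8,6.51
blood_whole,0.8,7.86
cortical_bone,0.8,14.12
brain,0.8,7.74
breast_tissue,0.8,7.13
eye_lens,0.8,7.38
lung_tissue,0.8,7.74
skeletal_muscle,0.8,7.72
ovary,0.8,7.68
testis,0.8,7.65
soft_tissue,0.8,7.72
soft_tissue_4component,0.8,7.36
adipose_tissue,1.0,6.51
blood_whole,1.0,7.86
cortical_bone,1.0,14.12
brain,1.0,7.74
breast_tissue,1.0,7.13
eye_lens,1.0,7.38
lung_tissue,1.0,7.74
skeletal_muscle,1.0,7.72
ovary,1.0,7.68
testis,1.0,7.65
soft_tissue,1.0,7.72
soft_tissue_4component,1.0,7.36
adipose_tissue,1.5,5.56
blood_whole,1.5,6.65
cortical_bone,1.5,11.43
brain,1.5,6.55
breast_tissue,1.5,6.13
eye_lens,1.5,6.47
lung_tissue,1.5,6.64
skeletal_muscle,1.5,6.58
ovary,1.5,6.63
testis,1.5,6.6
soft_tissue,1.5,6.59
soft_tissue_4component,1.5,6.55
adipose_tissue,2.0,5.53
blood_whole,2.0,6.59
cortical_bone,2.0,10.78
brain,2.0,6.49
breast_tissue,2.0,6.09
eye_lens,2.0,6.43
lung_tissue,2.0,6.59
skeletal_muscle,2.0,6.53
ovary,2.0,6.58
testis,2.0,6.55
soft_tissue,2.0,6.53
soft_tissue_4component,2.0,6.51
adipose_tissue,3.0,5.52
blood_whole,3.0,6.57
cortical_bone,3.0,10.61
brain,3.0,6.48
breast_tissue,3.0,6.08
eye_lens,3.0,6.42
lung_tissue,3.0,6.57
skeletal_muscle,3.0,6.52
ovary,3.0,6.57
testis,3.0,6.54
soft_tissue,3.0,6.52
soft_tissue_4component,3.0,6.51
adipose_tissue,4.0,5.51
blood_whole,4.0,6.57
cortical_bone,4.0,10.56
brain,4.0,6.47
breast_tissue,4.0,6.07
eye_lens,4.0,6.42
lung_tissue,4.0,6.57
skeletal_muscle,4.0,6.51
ovary,4.0,6.56
testis,4.0,6.53
soft_tissue,4.0,6.52
soft_tissue_4component,4.0,6.5
adipose_tissue,5.0,5.51
blood_whole,5.0,6.57
cortical_bone,5.0,10.53
brain,5.0,6.47
breast_tissue,5.0,6.07
eye_lens,5.0,6.41
lung_tissue,5.0,6.57
skeletal_muscle,5.0,6.51
ovary,5.0,6.56
testis,5.0,6.53
soft_tissue,5.0,6.51
soft_tissue_4component,5.0,6.5
adipose_tissue,6.0,5.51
blood_whole,6.0,6.56
cortical_bone,6.0,10.52
brain,6.0,6.47
breast_tissue,6.0,6.07
eye_lens,6.0,6.41
lung_tissue,6.0,6.56
skeletal_muscle,6.0,6.5
ovary,6.0,6.55
testis,6.0,6.53
soft_tissue,6.0,6.51
soft_tissue_4component,6.0,6.5
adipose_tissue,8.0,5.51
blood_whole,8.0,6.56
cortical_bone,8.0,10.51
brain,8.0,6.46
breast_tissue,8.0,6.06
eye_lens,8.0,6.41
lung_tissue,8.0,6.56
skeletal_muscle,8.0,6.5
ovary,8.0,6.55
testis,8.0,6.53
soft_tissue,8.0,6.51
soft_tissue_4component,8.0,6.49
adipose_tissue,10.0,5.51
blood_whole,10.0,6.56
cortical_bone,10.0,10.5
brain,10.0,6.46
breast_tissue,10.0,6.06
eye_lens,10.0,6.41
lung_tissue,10.0,6.56
skeletal_muscle,10.0,6.5
ovary,10.0,6.55
testis,10.0,6.52
soft_tissue,10.0,6.5
soft_tissue_4component,10.0,6.49
adipose_tissue,15.0,5.51
blood_whole,15.0,6.55
cortical_bone,15.0,10.49
brain,15.0,6.46
breast_tissue,15.0,6.06
eye_lens,15.0,6.4
lung_tissue,15.0,6.55
skeletal_muscle,15.0,6.49
ovary,15.0,6.54
testis,15.0,6.52
soft_tissue,15.0,6.5
soft_tissue_4component,15.0,6.49
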