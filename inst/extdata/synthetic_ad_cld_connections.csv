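source,target,polarity
Amyloid beta burden,Cerebral endothelial dysfunction,+
Amyloid beta burden,Neuroinflammation,+
Amyloid beta burden,Neuronal dysfunction,+
Amyloid beta burden,Tau pathology,+
ApoE-4 carriership,Amyloid beta burden,+
ApoE-4 carriership,Dyslipidemia,+
ApoE-4 carriership,Neuroinflammation,+
ApoE-4 carriership,Tau pathology,+
Brain atrophy,Cognitive functioning,-
Brain atrophy,Daily functioning,-
Brain perfusion,Cerebral endothelial dysfunction,-
Brain perfusion,Cognitive functioning,+
Brain perfusion,Neuronal dysfunction,-
Cerebral endothelial dysfunction,Amyloid beta burden,+
Cerebral endothelial dysfunction,Brain perfusion,-
Cerebral endothelial dysfunction,Lacunar infarcts,+
Cerebral endothelial dysfunction,Microbleeds,+
Cerebral endothelial dysfunction,White matter hyperintensities,+
Circadian misalignment,Experienced stress,+
Circadian misalignment,Glymphatic functioning,-
Circadian misalignment,Oxidative stress,+
Circadian misalignment,Sleep quality,-
Cognitive functioning,Depressive symptoms,-
Cognitive functioning,Engagement in cognitively demanding tasks,+
Cognitive functioning,Physical activity,+
DNA methylation,Neuronal dysfunction,+
Daily functioning,Social relationships,+
Depressive symptoms,Cognitive functioning,-
Depressive symptoms,Experienced stress,+
Depressive symptoms,Morbidity burden,+
Depressive symptoms,Physical activity,-
Depressive symptoms,Sleep quality,-
Depressive symptoms,Social relationships,-
Diabetes,Cerebral endothelial dysfunction,+
Diabetes,Dyslipidemia,+
Diabetes,Morbidity burden,+
Diabetes,Neuronal dysfunction,+
Diabetes,Systemic inflammation,+
Diabetes,White matter hyperintensities,+
Dyslipidemia,Cerebral endothelial dysfunction,+
Dyslipidemia,Morbidity burden,+
Education level,Cognitive functioning,+
Education level,Engagement in cognitively demanding tasks,+
Education level,Healthy dietary patterns,+
Education level,Physical activity,+
Education level,Smoking,-
Education level,Social relationships,+
Engagement in cognitively demanding tasks,Neuronal connectivity,+
Excessive alcohol use,DNA methylation,+
Excessive alcohol use,Hypertension,+
Excessive alcohol use,Morbidity burden,+
Excessive alcohol use,Oxidative stress,+
Excessive alcohol use,Social relationships,-
Experienced stress,Depressive symptoms,+
Experienced stress,Hypertension,+
Experienced stress,Sleep quality,-
Experienced stress,Smoking,+
Experienced stress,Systemic inflammation,+
Frailty,Daily functioning,-
Frailty,Motor function,-
Glymphatic functioning,Amyloid beta burden,-
Glymphatic functioning,Tau pathology,-
Head trauma,Amyloid beta burden,+
Head trauma,Microbleeds,+
Head trauma,Neuroinflammation,+
Head trauma,Neuronal dysfunction,+
Healthy dietary patterns,Diabetes,-
Healthy dietary patterns,Dyslipidemia,-
Healthy dietary patterns,Hypertension,-
Healthy dietary patterns,Obesity,-
Healthy dietary patterns,Oxidative stress,-
Healthy dietary patterns,Systemic inflammation,-
Hypertension,Cerebral endothelial dysfunction,+
Hypertension,Lacunar infarcts,+
Hypertension,Microbleeds,+
Hypertension,Morbidity burden,+
Hypertension,White matter hyperintensities,+
Lacunar infarcts,Brain atrophy,+
Lacunar infarcts,Motor function,-
Microbleeds,Brain atrophy,+
Microbleeds,Neuronal dysfunction,+
Morbidity burden,Daily functioning,-
Morbidity burden,Frailty,+
Morbidity burden,Motor function,-
Morbidity burden,Systemic inflammation,+
Motor function,Daily functioning,+
Motor function,Physical activity,+
Neuroinflammation,Amyloid beta burden,+
Neuroinflammation,Neuronal dysfunction,+
Neuroinflammation,Oxidative stress,+
Neuronal connectivity,Cognitive functioning,+
Neuronal dysfunction,Circadian misalignment,+
Neuronal dysfunction,Cognitive functioning,-
Neuronal dysfunction,Daily functioning,-
Neuronal dysfunction,Motor function,-
Neuronal dysfunction,Neuronal loss,+
Neuronal dysfunction,Sleep quality,-
Neuronal loss,Brain atrophy,+
Neuronal loss,Cognitive functioning,-
Neuronal loss,Neuronal connectivity,-
Obesity,Diabetes,+
Obesity,Dyslipidemia,+
Obesity,Hypertension,+
Obesity,Morbidity burden,+
Obesity,Motor function,-
Obesity,Sleep quality,-
Obesity,Systemic inflammation,+
Oxidative stress,Cerebral endothelial dysfunction,+
Oxidative stress,Neuroinflammation,+
Oxidative stress,Neuronal dysfunction,+
Physical activity,Brain perfusion,+
Physical activity,Depressive symptoms,-
Physical activity,Diabetes,-
Physical activity,Dyslipidemia,-
Physical activity,Hypertension,-
Physical activity,Morbidity burden,-
Physical activity,Motor function,+
Physical activity,Neuronal connectivity,+
Physical activity,Obesity,-
Physical activity,Sleep quality,+
Physical activity,Systemic inflammation,-
Sleep quality,Cognitive functioning,+
Sleep quality,Depressive symptoms,-
Sleep quality,Experienced stress,-
Sleep quality,Glymphatic functioning,+
Sleep quality,Social relationships,+
Sleep quality,Systemic inflammation,-
Smoking,Cerebral endothelial dysfunction,+
Smoking,DNA methylation,+
Smoking,Hypertension,+
Smoking,Morbidity burden,+
Smoking,Oxidative stress,+
Smoking,Systemic inflammation,+
Social relationships,Cognitive functioning,+
Social relationships,Depressive symptoms,-
Social relationships,Engagement in cognitively demanding tasks,+
Social relationships,Excessive alcohol use,-
Social relationships,Experienced stress,-
Social relationships,Morbidity burden,-
Social relationships,Physical activity,+
Social relationships,Sleep quality,+
Systemic inflammation,Cerebral endothelial dysfunction,+
Systemic inflammation,Morbidity burden,+
Systemic inflammation,Neuroinflammation,+
Systemic inflammation,Oxidative stress,+
Tau pathology,Neuronal connectivity,-
Tau pathology,Neuronal dysfunction,+
Tau pathology,Neuronal loss,+
White matter hyperintensities,Brain atrophy,+
White matter hyperintensities,Neuronal dysfunction,+
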