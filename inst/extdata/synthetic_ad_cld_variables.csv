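name,category,scale,definition
Amyloid beta burden,brain,cellular,Accumulation of aggregated amyloid-beta protein in brain tissue
ApoE-4 carriership,physical,person,Carrying at least one APOE epsilon-4 allele
Brain atrophy,brain,organ,Structural loss of brain tissue volume
Brain perfusion,brain,organ,Cerebral blood flow supplying brain tissue
Cerebral endothelial dysfunction,brain,organ,Impaired function of the cerebrovascular endothelium
Circadian misalignment,brain,organ,Disruption of endogenous circadian rhythms
Cognitive functioning,psychosocial,person,Global cognitive performance
DNA methylation,brain,cellular,Aberrant epigenetic methylation patterns in brain tissue
Daily functioning,psychosocial,person,Ability to perform activities of daily living
Depressive symptoms,psychosocial,person,Severity of depressive symptomatology
Diabetes,physical,person,Type 2 diabetes mellitus / impaired glucose regulation
Dyslipidemia,physical,person,Unfavourable blood lipid profile
Education level,psychosocial,person,Attained formal education
Engagement in cognitively demanding tasks,psychosocial,person,Participation in cognitively stimulating activities
Excessive alcohol use,physical,person,Alcohol consumption above low-risk limits
Experienced stress,psychosocial,person,Perceived psychological stress
Frailty,physical,person,Age-related loss of physiological reserve
Glymphatic functioning,brain,cellular,Clearance of metabolic waste via the glymphatic system
Head trauma,physical,person,History of traumatic brain injury
Healthy dietary patterns,physical,person,Adherence to a healthy diet
Hypertension,physical,person,Chronically elevated blood pressure
Lacunar infarcts,brain,organ,Small subcortical ischaemic infarcts
Microbleeds,brain,organ,Small chronic cerebral haemorrhages
Morbidity burden,physical,person,Number and severity of chronic somatic diseases
Motor function,physical,person,"Capacity for movement, gait and balance"
Neuroinflammation,brain,cellular,Microglial and astrocytic inflammatory activation in the brain
Neuronal connectivity,brain,cellular,Synaptic and network connectivity between neurons
Neuronal dysfunction,brain,cellular,Impaired neuronal signalling and metabolism (aggregate)
Neuronal loss,brain,cellular,Death of neurons; the ultimate state of neuronal dysfunction
Obesity,physical,person,Excess body fat
Oxidative stress,brain,cellular,Excess reactive oxygen species relative to antioxidant capacity
Physical activity,physical,person,Habitual bodily movement and exercise
Sleep quality,psychosocial,person,Restorative quality of habitual sleep
Smoking,physical,person,Tobacco smoking
Social relationships,psychosocial,person,Quantity and quality of social contacts
Systemic inflammation,physical,person,Chronic low-grade inflammation outside the brain
Tau pathology,brain,cellular,Hyperphosphorylated tau and neurofibrillary tangle formation
White matter hyperintensities,brain,organ,Small-vessel white matter lesions visible on MRI
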