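loop,first_variable,second_variable,third_variable
RD1,Amyloid beta burden,Neuroinflammation,
RD2,Oxidative stress,Neuroinflammation,
RD3,Amyloid beta burden,Cerebral endothelial dysfunction,
RD4,Brain perfusion,Cerebral endothelial dysfunction,
RD5,Systemic inflammation,Morbidity burden,
RD6,Motor function,Physical activity,
RD7,Physical activity,Depressive symptoms,
RD8,Excessive alcohol use,Social relationships,
RD9,Sleep quality,Experienced stress,
RD10,Depressive symptoms,Experienced stress,
RD11,Depressive symptoms,Cognitive functioning,
RD12,Depressive symptoms,Sleep quality,
RD13,Depressive symptoms,Social relationships,
RD14,Sleep quality,Social relationships,
RI1,Oxidative stress,Neuronal dysfunction,Circadian misalignment
RI2,Physical activity,Neuronal connectivity,Cognitive functioning
RI3,Obesity,Motor function,Physical activity
RI4,Morbidity burden,Motor function,Physical activity
RI5,Brain perfusion,Physical activity,Cognitive functioning
RI6,Neuronal connectivity,Cognitive functioning,Engagement in cognitively demanding tasks
RI7,Morbidity burden,Daily functioning,Social relationships
RI8,Physical activity,Sleep quality,Cognitive functioning
RI9,Physical activity,Depressive symptoms,Social relationships
RI10,Physical activity,Sleep quality,Social relationships
RI11,Experienced stress,Depressive symptoms,Sleep quality
RI12,Experienced stress,Sleep quality,Depressive symptoms
RI13,Experienced stress,Depressive symptoms,Social relationships
RI14,Social relationships,Depressive symptoms,Cognitive functioning
RI15,Depressive symptoms,Sleep quality,Social relationships
RI16,Depressive symptoms,Social relationships,Sleep quality
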