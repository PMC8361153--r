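characteristic,class,count
dental_class,Class_I,7
dental_class,Class_II,10
dental_class,Class_III,1
skeletal_class,Class_I,5
skeletal_class,Class_II,8
skeletal_class,Class_III,5
vertical_type,Hypodivergent,0
vertical_type,Normodivergent,12
vertical_type,Hyperdivergent,6
transversal_type,Narrow,0
transversal_type,Normal,17
transversal_type,Wide,1
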