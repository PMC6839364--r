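cohort	mode	organ_id	mean_dose_mGy	sd_mGy	volume_cm3	volume_sd_cm3
lung	thorax	lung	7.6	1.2	2259.0	722.5
lung	thorax	stomach	3.6	2.1	229.4	175.7
lung	thorax	bone_marrow	10.8	2.2	324.6	118.1
lung	thorax	esophagus	7.5	1.8	33.7	13.1
lung	thorax	liver	4.9	2.3	1049.4	218.9
lung	thorax	thyroid	10.1	10.8	18.4	15.5
lung	thorax	bone_surface	12.7	2.2	990.5	321.0
lung	thorax	skin	4.4	0.6	931.4	179.5
lung	thorax	adrenals	2.8	2.1	3.0	1.6
lung	thorax	gallbladder	2.2	2.0	12.7	13.1
lung	thorax	heart	8.5	2.1	712.3	263.5
lung	thorax	intestine	1.5	0.8	556.0	262.7
lung	thorax	kidney	1.3	1.1	251.9	79.6
lung	thorax	pancreas	2.3	1.8	32.1	14.1
lung	thorax	spleen	4.4	3.0	129.5	85.8
lung	pelvis	lung	30.5	4.6	2259.0	722.5
lung	pelvis	stomach	14.3	8.2	229.4	175.7
lung	pelvis	bone_marrow	43.1	8.7	324.6	118.1
lung	pelvis	esophagus	29.9	7.2	33.7	13.1
lung	pelvis	liver	19.6	9.3	1049.4	218.9
lung	pelvis	thyroid	40.2	43.2	18.4	15.5
lung	pelvis	bone_surface	51.0	8.6	990.5	321.0
lung	pelvis	skin	17.6	2.6	931.4	179.5
lung	pelvis	adrenals	11.2	8.5	3.0	1.6
lung	pelvis	gallbladder	8.8	7.9	12.7	13.1
lung	pelvis	heart	34.2	8.2	712.3	263.5
lung	pelvis	intestine	5.9	3.2	556.0	262.7
lung	pelvis	kidney	5.4	4.5	251.9	79.6
lung	pelvis	pancreas	9.1	7.2	32.1	14.1
lung	pelvis	spleen	17.6	11.9	129.5	85.8
lung	fourD	lung	14.3	2.2	2259.0	722.5
lung	fourD	stomach	6.7	3.8	229.4	175.7
lung	fourD	bone_marrow	20.2	4.1	324.6	118.1
lung	fourD	esophagus	14.0	3.3	33.7	13.1
lung	fourD	liver	9.1	4.4	1049.4	218.9
lung	fourD	thyroid	18.8	20.2	18.4	15.5
lung	fourD	bone_surface	23.8	4.0	990.5	321.0
lung	fourD	skin	8.2	1.2	931.4	179.5
lung	fourD	adrenals	5.2	4.0	3.0	1.6
lung	fourD	gallbladder	4.1	3.7	12.7	13.1
lung	fourD	heart	16.0	3.8	712.3	263.5
lung	fourD	intestine	2.7	1.5	556.0	262.7
lung	fourD	kidney	2.5	2.1	251.9	79.6
lung	fourD	pancreas	4.2	3.4	32.1	14.1
lung	fourD	spleen	8.2	5.6	129.5	85.8
liver	thorax	lung	4.2	0.9	2259.0	722.5
liver	thorax	stomach	9.6	2.6	229.4	175.7
liver	thorax	bone_marrow	8.1	3.3	324.6	118.1
liver	thorax	esophagus	4.7	0.9	33.7	13.1
liver	thorax	liver	12.8	3.0	1049.4	218.9
liver	thorax	bone_surface	10.7	2.5	990.5	321.0
liver	thorax	skin	5.2	1.2	931.4	179.5
liver	thorax	adrenals	8.7	2.3	3.0	1.6
liver	thorax	gallbladder	8.6	3.9	12.7	13.1
liver	thorax	heart	13.1	3.1	712.3	263.5
liver	thorax	intestine	5.8	2.1	556.0	262.7
liver	thorax	kidney	10.1	3.4	251.9	79.6
liver	thorax	pancreas	13.5	3.5	32.1	14.1
liver	thorax	spleen	14.9	2.9	129.5	85.8
liver	pelvis	lung	16.7	3.6	2259.0	722.5
liver	pelvis	stomach	38.6	10.3	229.4	175.7
liver	pelvis	bone_marrow	32.4	13.4	324.6	118.1
liver	pelvis	esophagus	18.9	3.8	33.7	13.1
liver	pelvis	liver	51.3	12.1	1049.4	218.9
liver	pelvis	bone_surface	42.8	10.0	990.5	321.0
liver	pelvis	skin	20.9	4.8	931.4	179.5
liver	pelvis	adrenals	34.8	9.0	3.0	1.6
liver	pelvis	gallbladder	34.3	15.6	12.7	13.1
liver	pelvis	heart	52.3	12.3	712.3	263.5
liver	pelvis	intestine	23.2	8.3	556.0	262.7
liver	pelvis	kidney	40.5	13.7	251.9	79.6
liver	pelvis	pancreas	54.1	14.0	32.1	14.1
liver	pelvis	spleen	59.5	11.6	129.5	85.8
liver	fourD	lung	7.8	1.7	2259.0	722.5
liver	fourD	stomach	18.0	4.8	229.4	175.7
liver	fourD	bone_marrow	15.1	6.2	324.6	118.1
liver	fourD	esophagus	8.8	1.8	33.7	13.1
liver	fourD	liver	24.0	5.6	1049.4	218.9
liver	fourD	bone_surface	20.0	4.7	990.5	321.0
liver	fourD	skin	9.8	2.2	931.4	179.5
liver	fourD	adrenals	16.3	4.2	3.0	1.6
liver	fourD	gallbladder	16.0	7.3	12.7	13.1
liver	fourD	heart	24.5	5.8	712.3	263.5
liver	fourD	intestine	10.8	3.9	556.0	262.7
liver	fourD	kidney	18.9	6.4	251.9	79.6
liver	fourD	pancreas	25.3	6.5	32.1	14.1
liver	fourD	spleen	27.8	5.4	129.5	85.8
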