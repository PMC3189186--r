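>mfam01|human|human_mfam01
ANTCNLQCGPSNNKCTTQAKKCVKQPTKQALNQCLCLCVACANLKQNAAKVANSNKLSKSGNCSCCLTNSNSLCVTQVCGPTVGAQPALLTASVLTLCQSVNPVTVVQAKTCVVTQNLCPKPLKPKLACNPVAGKLAGCT
>mfam01|mouse|mouse_mfam01
AERRRLELGRERRGGTREALRPEERRRNEALRQSEEEVRRLRRLAQEAANVERSRQREERRNPEEEREPSNRLEVEQEPESTVEAQEALETEEVEELEQRREPVRRVQEEEVREERNLEEQPLSRNRAENREPGELRGRE
>mfam01|cow|cow_mfam01
AETCRLELGRYNNGGTTQYNHPVQRPTKEALNQCLSLCVRCRNLAQNHANVANSHQLSKSRNCGQCRTHSNSLEVTQVPEYTVEAQHALHTAHVLELCQRVNPTDVVQLKTHVVTQNLQEKPLKLKRAPNPVHGKLAGVA
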