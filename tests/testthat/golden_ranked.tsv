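# condock 1.0.0
# config: dialect=swissdock background=uniform cutoff=3.5 weighting=mass threshold=4 hash=4b84e786874bea29a1bf38355f26e84c
# inputs: receptor.pdb=01c723b239bf8849c775dba71e422bca poses_swissdock.pdb=4e30806dfe135323627d080496bee2e2 grades.txt=7c63f76a343c1e2471cc212a1d2ca6ea
pose_id	energy_score	conservation_score	condock_score	rank	n_site_residues	site_residues
c8.e0	-1492.157100	0.888889	-1326.361867	1	7	A:13:;A:24:;A:25:;A:26:;A:36:;A:37:;A:48:
c0.e0	-1561.376100	0.222222	-346.972467	2	7	A:4:;A:5:;A:15:;A:16:;A:17:;A:28:;A:29:
c7.e0	-1553.127200	0.222222	-345.139378	3	3	A:46:;A:58:;A:59:
c1.e0	-1549.282000	0.222222	-344.284889	4	4	A:7:;A:8:;A:19:;A:20:
c6.e0	-1523.579500	0.222222	-338.573222	5	3	A:7:;A:8:;A:19:
c5.e0	-1498.472100	0.222222	-332.993800	6	5	A:40:;A:41:;A:52:;A:53:;A:54:
c2.e0	-1491.455400	0.222222	-331.434533	7	3	A:42:;A:54:;A:55:
c3.e0	-1466.929000	0.222222	-325.984222	8	3	A:43:;A:55:;A:56:
c4.e0	-1346.314900	0.222222	-299.181089	9	3	A:43:;A:55:;A:56:
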